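#' Per-site allele frequencies for the three-taxon differentiation analysis
#'
#' Combines the two platforms' reads per taxon, keeps only sites covered by
#' at least `min_depth` reads in ALL three taxa, determines the majority and
#' focal-variant alleles from the pooled three-taxon counts, discards sites
#' whose minor allele appears exactly once in the pooled counts (combined
#' singletons, mostly sequencing errors) and sites that are monomorphic
#' overall, and returns per-taxon frequencies of the majority allele
#' (`p`; the focal variant has frequency `q = 1 - p`; rarer third/fourth
#' alleles are ignored).
#'
#' @param counts_by_taxon named list of `pool_counts` objects for taxa
#'   `R`, `I`, `J`.
#' @param min_depth minimum combined read depth per taxon.
#' @return data.frame with `pos` (0-based), `p_R`, `p_I`, `p_J`, `depth_R`,
#'   `depth_I`, `depth_J`.
#' @export
site_frequencies <- function(counts_by_taxon, min_depth = 10) {
  need <- c("R", "I", "J")
  if (!all(need %in% names(counts_by_taxon))) stop("missing taxon")
  comb <- lapply(counts_by_taxon[need], function(pc)
    pc$counts[[1]] + pc$counts[[2]])
  depth <- lapply(comb, rowSums)
  keep <- depth$R >= min_depth & depth$I >= min_depth & depth$J >= min_depth
  total <- comb$R + comb$I + comb$J
  L <- nrow(total)
  maj <- max.col(total, ties.method = "first")
  idx <- cbind(seq_len(L), maj)
  t2 <- total; t2[idx] <- -1L
  focal <- max.col(t2, ties.method = "first")
  fidx <- cbind(seq_len(L), focal)
  minor_count <- total[fidx]
  keep <- keep & minor_count >= 2          # polymorphic, no combined singleton
  w <- which(keep)
  pf <- function(tx) {
    two <- comb[[tx]][w, , drop = FALSE]
    maj_c <- two[cbind(seq_along(w), maj[w])]
    foc_c <- two[cbind(seq_along(w), focal[w])]
    tot <- maj_c + foc_c
    ifelse(tot > 0, maj_c / tot, NA_real_)
  }
  data.frame(pos = w - 1L, p_R = pf("R"), p_I = pf("I"), p_J = pf("J"),
             depth_R = depth$R[w], depth_I = depth$I[w],
             depth_J = depth$J[w])
}

#' Mean genetic distance between two populations over a site set
#'
#' Per SNP, the distance is `p1*q2 + p2*q1` -- the probability that two
#' sequences, one drawn at random from each population, differ at the site.
#' The segment distance is the unweighted mean over SNP positions, in
#' \[0, 1\].
#'
#' @param freqs_pop1,freqs_pop2 allele frequencies (same allele, same sites).
#' @return mean distance (scalar).
#' @examples
#' genetic_distance(1, 0)        # fixed difference -> 1
#' genetic_distance(0.5, 0.5)    # -> 0.5
#' @export
genetic_distance <- function(freqs_pop1, freqs_pop2) {
  if (length(freqs_pop1) == 0) stop("empty site set")
  stopifnot(length(freqs_pop1) == length(freqs_pop2))
  mean(freqs_pop1 * (1 - freqs_pop2) + freqs_pop2 * (1 - freqs_pop1))
}

#' Weir-Cockerham Fst for haploid allele-frequency data
#'
#' Moment (ANOVA) estimator for two populations of haploid lineages: with
#' sample sizes `n_a`, `n_b` and frequencies `p_a`, `p_b` of the same allele,
#'
#' \deqn{MSP = n_a (p_a - \bar p)^2 + n_b (p_b - \bar p)^2}
#' \deqn{MSG = (n_a p_a (1-p_a) + n_b p_b (1-p_b)) / (n_a + n_b - 2)}
#' \deqn{n_c = n_a + n_b - (n_a^2 + n_b^2)/(n_a + n_b)}
#' \deqn{F_{st} = (MSP - MSG) / (MSP + (n_c - 1) MSG)}
#'
#' with \eqn{\bar p} the weighted mean frequency. Estimates below 0 are
#' clamped to 0 and above 1 to 1, so `Fst = 0` means no differentiation and
#' `Fst = 1` complete differentiation. Vectorised over sites.
#'
#' @param p_a,p_b allele frequencies per site.
#' @param n_a,n_b haploid sample sizes (>= 2).
#' @return per-site Fst in \[0, 1\].
#' @export
weir_fst <- function(p_a, n_a, p_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2)
  mono <- (p_a == 0 & p_b == 0) | (p_a == 1 & p_b == 1)
  if (any(mono))
    stop("Fst undefined at sites monomorphic in the pooled pair; pre-filter")
  pbar <- (n_a * p_a + n_b * p_b) / (n_a + n_b)
  msp <- n_a * (p_a - pbar)^2 + n_b * (p_b - pbar)^2
  msg <- (n_a * p_a * (1 - p_a) + n_b * p_b * (1 - p_b)) / (n_a + n_b - 2)
  nc <- n_a + n_b - (n_a^2 + n_b^2) / (n_a + n_b)
  fst <- (msp - msg) / (msp + (nc - 1) * msg)
  pmin(pmax(fst, 0), 1)
}

#' Per-site Fst records for the three taxon pairs
#'
#' Builds the three pairwise Fst values (I-J, R-I, R-J) from per-site
#' frequencies. Sites monomorphic within a pooled pair (both populations
#' fixed for the same allele) are assigned Fst = 0 for that pair: such sites
#' show no differentiation, and introgression-shared sites -- where the two
#' cultivars are fixed for the same allele while the wild taxon still
#' segregates -- are exactly the signal the conditional analysis measures.
#'
#' @param freqs data.frame with `p_R`, `p_I`, `p_J` (from
#'   [site_frequencies()] or a haplotype pipeline) plus any extra columns,
#'   which are carried through.
#' @param n_R,n_I,n_J haploid sample sizes.
#' @return `freqs` with columns `fst_IJ`, `fst_RI`, `fst_RJ` appended.
#' @export
fst_site_records <- function(freqs, n_R = 46, n_I = 22, n_J = 21) {
  pair <- function(p1, np1, p2, np2) {
    mono <- (p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1)
    out <- numeric(length(p1))
    if (any(!mono))
      out[!mono] <- weir_fst(p1[!mono], np1, p2[!mono], np2)
    out
  }
  freqs$fst_IJ <- pair(freqs$p_I, n_I, freqs$p_J, n_J)
  freqs$fst_RI <- pair(freqs$p_R, n_R, freqs$p_I, n_I)
  freqs$fst_RJ <- pair(freqs$p_R, n_R, freqs$p_J, n_J)
  freqs
}

#' Condition on strong wild/cultivar differentiation
#'
#' Keeps records with `Fst(R, I) >= min_fst_RI`. Sites where the two most
#' polymorphic taxa (R and I) are weakly differentiated carry little
#' information about which domestication genealogy a region follows; the
#' conditional analysis focuses on the informative sites. A threshold of 0
#' reproduces the all-sites analysis.
#'
#' @param records data.frame with an `fst_RI` column.
#' @param min_fst_RI threshold (kept if `>=`).
#' @return subset of `records`.
#' @export
conditional_sites <- function(records, min_fst_RI = 0.5) {
  records[records$fst_RI >= min_fst_RI, , drop = FALSE]
}

#' Maximum ECDF distance (two-sample Kolmogorov-Smirnov D)
#'
#' `D = max_x |F_subset(x) - F_background(x)|` over the pooled sample points:
#' the largest vertical distance between the two empirical cumulative
#' distribution curves.
#'
#' @param values_subset,values_background numeric samples (non-empty).
#' @return D in \[0, 1\].
#' @examples
#' ecdf_d_statistic(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))  # 1/3
#' @export
ecdf_d_statistic <- function(values_subset, values_background) {
  if (length(values_subset) == 0 || length(values_background) == 0)
    stop("empty sample")
  z <- sort(c(values_subset, values_background))
  max(abs(stats::ecdf(values_subset)(z) - stats::ecdf(values_background)(z)))
}

#' Extract per-site frequencies and Fst records from a haplotype genome
#'
#' Pipeline used on simulated data: per locus, derived-allele frequencies per
#' taxon at every segregating column, with sites whose pooled minor-allele
#' count is 1 discarded (the combined-singleton rule), then the three
#' pairwise Fst values.
#'
#' @param genome list of `haplotype_sample` loci.
#' @return data.frame with `locus`, `pos`, `p_R`, `p_I`, `p_J`, the Fst
#'   triplet, and `derived_count`.
#' @export
genome_fst_records <- function(genome) {
  recs <- lapply(seq_along(genome), function(i) {
    smp <- genome[[i]]
    if (ncol(smp$mat) == 0) return(NULL)
    cnt <- colSums(smp$mat)
    n_tot <- nrow(smp$mat)
    keep <- pmin(cnt, n_tot - cnt) >= 2      # drop combined singletons
    if (!any(keep)) return(NULL)
    mat <- smp$mat[, keep, drop = FALSE]
    fr <- function(tx) colMeans(mat[smp$taxa == tx, , drop = FALSE])
    data.frame(locus = i, pos = smp$positions[keep],
               p_R = fr("R"), p_I = fr("I"), p_J = fr("J"),
               derived_count = cnt[keep])
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    return(data.frame(locus = integer(), pos = numeric(), p_R = numeric(),
                      p_I = numeric(), p_J = numeric(),
                      derived_count = integer(), fst_IJ = numeric(),
                      fst_RI = numeric(), fst_RJ = numeric()))
  ns <- table(genome[[1]]$taxa)
  fst_site_records(recs, n_R = ns[["R"]], n_I = ns[["I"]], n_J = ns[["J"]])
}
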
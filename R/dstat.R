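#' Configuration for the conditional-D genealogy pipeline
#'
#' Bundles the settings shared by the observed-data analysis and its
#' simulated null: how many loci a dataset has, how low-diversity-region
#' analogues are designated inside it (the lowest `ldr_fraction` of loci by
#' the designation taxon's Watterson theta, mirroring the bottom-5% rule),
#' and the conditioning threshold on Fst(R, I).
#'
#' @param n_loci loci per dataset.
#' @param locus_length locus length in bp.
#' @param sample_sizes named haploid sample sizes (`n_R`, `n_I`, `n_J`).
#' @param ldr_fraction fraction of loci designated low-diversity.
#' @param min_fst_RI conditioning threshold (see [conditional_sites()]).
#' @param diversity_taxon taxon whose per-locus diversity ranks loci.
#' @return a list of class `d_pipeline_config`.
#' @export
d_pipeline_config <- function(n_loci = 200, locus_length = 10000,
                              sample_sizes = c(n_R = 46, n_I = 22, n_J = 21),
                              ldr_fraction = 0.05, min_fst_RI = 0.5,
                              diversity_taxon = "I") {
  stopifnot(n_loci >= 1, locus_length > 0, ldr_fraction > 0,
            ldr_fraction <= 1)
  structure(list(n_loci = n_loci, locus_length = locus_length,
                 sample_sizes = sample_sizes, ldr_fraction = ldr_fraction,
                 min_fst_RI = min_fst_RI, diversity_taxon = diversity_taxon),
            class = "d_pipeline_config")
}

#' Per-locus Watterson theta of one taxon in a haplotype genome
#'
#' @param genome list of `haplotype_sample` loci.
#' @param taxon taxon label.
#' @return theta per kb, one value per locus.
#' @export
locus_theta <- function(genome, taxon) {
  vapply(genome, function(smp) {
    rows <- smp$taxa == taxon
    n <- sum(rows)
    if (ncol(smp$mat) == 0) return(0)
    cnt <- colSums(smp$mat[rows, , drop = FALSE])
    watterson_theta(sum(cnt > 0 & cnt < n), n, smp$locus_length)
  }, numeric(1))
}

#' Conditional Fst D statistic of a multi-locus dataset
#'
#' Runs the full designation-and-comparison pipeline on a simulated (or
#' injected) genome: ranks loci by the designation taxon's diversity, marks
#' the lowest `ldr_fraction` as LDR analogues, computes per-site Fst records,
#' keeps sites with `Fst(R, I) >=` the conditioning threshold, and returns
#' the maximum ECDF distance between the `Fst(I, J)` distribution of the
#' LDR-analogue sites and that of the genomic background (all conditional
#' sites).
#'
#' @param genome list of `haplotype_sample` loci.
#' @param config a [d_pipeline_config()].
#' @return list with `D`, `ldr_loci` (indices), `n_subset`, `n_background`,
#'   `records` (the conditional site records with an `in_ldr` flag).
#' @export
conditional_fst_D <- function(genome, config = d_pipeline_config()) {
  theta <- locus_theta(genome, config$diversity_taxon)
  k <- ceiling(config$ldr_fraction * length(genome) - 1e-9)
  ldr <- sort(order(theta, seq_along(theta))[seq_len(k)])
  recs <- genome_fst_records(genome)
  recs <- conditional_sites(recs, config$min_fst_RI)
  recs$in_ldr <- recs$locus %in% ldr
  sub <- recs$fst_IJ[recs$in_ldr]
  bg <- recs$fst_IJ
  D <- if (length(sub) == 0 || length(bg) == 0) NA_real_
       else ecdf_d_statistic(sub, bg)
  list(D = D, ldr_loci = ldr, n_subset = length(sub),
       n_background = length(bg), records = recs)
}

#' Simulated null distribution of the conditional D statistic
#'
#' Per replicate, simulates a complete multi-locus three-taxon dataset under
#' ONE demographic history (cycling through `models` if several are given),
#' runs exactly the same LDR-designation, conditioning and D computation as
#' on observed data, and collects the replicate D values. The empirical
#' p-value of an observed D is `(1 + #\{null >= observed\}) / (1 + #null)`.
#'
#' @param models a `demographic_model` or list of them (the parameter
#'   combinations spanning the explored demographies).
#' @param reps_per_model replicates per model.
#' @param config a [d_pipeline_config()].
#' @param observed_D optional observed D to attach a p-value to.
#' @param seed optional integer seed.
#' @return object of class `d_stat_result`: list with `observed_D`,
#'   `null_D` (all replicate values), `max_null_D`, `p_value`, `n_null`.
#' @export
simulate_null_D <- function(models, reps_per_model, config = d_pipeline_config(),
                            observed_D = NA, seed = NULL) {
  if (inherits(models, "demographic_model")) models <- list(models)
  stopifnot(length(models) >= 1, reps_per_model >= 1)
  local_seed(seed)
  null_D <- vapply(seq_len(length(models) * reps_per_model), function(r) {
    m <- models[[(r - 1L) %% length(models) + 1L]]
    g <- simulate_three_taxon_genome(m, config$n_loci, config$locus_length,
                                     config$sample_sizes)
    conditional_fst_D(g, config)$D
  }, numeric(1))
  d_stat_result(observed_D, null_D)
}

#' Assemble a D-statistic test result
#'
#' @param observed_D observed D (may be `NA`).
#' @param null_D vector of null-replicate D values.
#' @return object of class `d_stat_result`.
#' @export
d_stat_result <- function(observed_D, null_D) {
  null_D <- null_D[!is.na(null_D)]
  p <- if (is.na(observed_D)) NA_real_
       else (1 + sum(null_D >= observed_D)) / (1 + length(null_D))
  structure(list(observed_D = observed_D, null_D = null_D,
                 max_null_D = if (length(null_D)) max(null_D) else NA_real_,
                 p_value = p, n_null = length(null_D)),
            class = "d_stat_result")
}

#' @export
print.d_stat_result <- function(x, ...) {
  cat(sprintf("Conditional D: observed = %.4g, null max = %.4g over %d replicates, p = %.4g\n",
              x$observed_D, x$max_null_D, x$n_null, x$p_value))
  invisible(x)
}

#' One-sided Kolmogorov-Smirnov screen of one genomic region
#'
#' Tests whether the region's `Fst(I, J)` values are stochastically smaller
#' than both its `Fst(R, J)` and its `Fst(R, I)` values (one-sided two-sample
#' KS tests, asymptotic p-values). The region is significant iff BOTH
#' p-values fall below `alpha` (nominal, uncorrected). Regions with fewer
#' than `min_sites` records are reported untestable, not significant.
#'
#' @param region_records data.frame of the region's Fst records (columns
#'   `fst_IJ`, `fst_RI`, `fst_RJ`).
#' @param alpha nominal significance level.
#' @param min_sites minimum SNP records required to test.
#' @param exact use exact small-sample KS p-values instead of asymptotic.
#' @return list with `p_vs_RJ`, `p_vs_RI`, `significant`, `testable`,
#'   `n_sites`.
#' @export
region_ks_test <- function(region_records, alpha = 0.05, min_sites = 10,
                           exact = FALSE) {
  n <- nrow(region_records)
  if (n < min_sites)
    return(list(p_vs_RJ = NA_real_, p_vs_RI = NA_real_, significant = FALSE,
                testable = FALSE, n_sites = n))
  # alternative = "greater": the CDF of x lies above that of y,
  # i.e. x stochastically smaller
  p1 <- suppressWarnings(ks.test(region_records$fst_IJ,
                                 region_records$fst_RJ,
                                 alternative = "greater", exact = exact))$p.value
  p2 <- suppressWarnings(ks.test(region_records$fst_IJ,
                                 region_records$fst_RI,
                                 alternative = "greater", exact = exact))$p.value
  list(p_vs_RJ = p1, p_vs_RI = p2,
       significant = p1 < alpha && p2 < alpha, testable = TRUE, n_sites = n)
}
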
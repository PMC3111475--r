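#' Simulate the two-phase genealogy of one locus
#'
#' Generates the coalescent genealogy of a sample from the three taxa under a
#' domestication model. The coalescent is partitioned into two phases: from
#' the present back to the domestication time the cultivar samples coalesce in
#' their bottlenecked populations with selfing-suppressed recombination (at
#' the default `selfing_rate = 1` the whole locus is non-recombining in this
#' phase, so every sub-segment shares the cultivar genealogy); beyond
#' domestication the locus is partitioned into non-recombining sub-segments
#' whose wild-phase genealogies are conditionally independent given the
#' lineages surviving at the domestication time.
#'
#' @param model a [demographic_model()].
#' @param locus_length locus length in bp (> 0).
#' @param sample_sizes named vector/list with haploid sample sizes `n_R`,
#'   `n_I`, `n_J` (each >= 0, total >= 2). Selfing cultivar accessions
#'   contribute one lineage each; outcrossing wild accessions two.
#' @param seed optional integer seed.
#' @return object of class `locus_genealogy`: a list of sub-segments, each
#'   with elements `start`, `end` (bp, half-open), `parent` (0-based node
#'   parent indices, -1 for the root), `time` (node times in `4 N_R`
#'   generations) and `n_leaves`; leaves are ordered R, I, J. Attributes
#'   carry the model, the locus length and the taxon labels.
#' @examples
#' m <- demographic_model("independent")
#' g <- two_phase_genealogy(m, 2000, c(n_R = 4, n_I = 3, n_J = 3), seed = 1)
#' length(g)  # number of non-recombining wild-phase sub-segments
#' @export
two_phase_genealogy <- function(model, locus_length,
                                sample_sizes = c(n_R = 46, n_I = 22, n_J = 21),
                                seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  if (!is.numeric(locus_length) || locus_length <= 0)
    stop("locus_length must be positive")
  ss <- as.list(sample_sizes)
  n_R <- ss$n_R %||% 0; n_I <- ss$n_I %||% 0; n_J <- ss$n_J %||% 0
  stopifnot(n_R >= 0, n_I >= 0, n_J >= 0, n_R + n_I + n_J >= 2)
  local_seed(seed)
  refresh <- model_breakpoint_rate(model) * (1 - model$selfing_rate)
  segs <- cpp_two_phase_locus(
    n_R = as.integer(n_R), n_I = as.integer(n_I), n_J = as.integer(n_J),
    c_I = model$N_I / model$N_R, c_J = model$N_J / model$N_R,
    c_D = model$N_D / model$N_R,
    topology = if (model$topology == "independent") 0L else 1L,
    T_split = model$T_split, T_d = model_T_dom(model),
    locus_length = locus_length,
    breakpoint_rate = model_breakpoint_rate(model),
    refresh_rate = refresh)
  taxa <- rep(c("R", "I", "J"), times = c(n_R, n_I, n_J))
  structure(segs, class = "locus_genealogy", model = model,
            locus_length = locus_length, taxa = taxa)
}

#' Overlay infinite-sites mutations on a simulated genealogy
#'
#' Mutations are placed as a Poisson process along every branch at rate
#' `theta` per site per unit branch length (time in `4 N_R` generations), so
#' for a single constant-size population `E[S] = a_n * theta * L`. Each
#' mutation creates one segregating 0/1 column; positions are uniform within
#' the mutated sub-segment.
#'
#' @param genealogies a `locus_genealogy` from [two_phase_genealogy()].
#' @param theta scaled per-site mutation rate; defaults to the model's
#'   `mut_rate_theta`.
#' @param seed optional integer seed.
#' @return a `haplotype_sample`: list with `positions` (0-based bp offsets,
#'   strictly increasing), `mat` (haplotype x site 0/1 matrix), `taxa`
#'   (leaf taxon labels) and `locus_length`.
#' @export
overlay_mutations <- function(genealogies, theta = NULL, seed = NULL) {
  stopifnot(inherits(genealogies, "locus_genealogy"))
  model <- attr(genealogies, "model")
  theta <- theta %||% model$mut_rate_theta
  if (theta < 0) stop("theta must be >= 0")
  local_seed(seed)
  res <- cpp_overlay_mutations(unclass(genealogies), theta)
  pos <- res$positions
  mat <- res$mat
  # infinite-sites positions tie with probability ~0; enforce strict order
  if (anyDuplicated(pos)) {
    keep <- !duplicated(pos)
    pos <- pos[keep]
    mat <- mat[, keep, drop = FALSE]
  }
  haplotype_sample(pos, mat, attr(genealogies, "taxa"),
                   attr(genealogies, "locus_length"))
}

#' Construct a haplotype sample
#'
#' @param positions 0-based bp offsets, strictly increasing.
#' @param mat haplotype x site 0/1 integer matrix.
#' @param taxa taxon label per haplotype row.
#' @param locus_length locus length in bp.
#' @return object of class `haplotype_sample`.
#' @export
haplotype_sample <- function(positions, mat, taxa, locus_length) {
  mat <- as.matrix(mat)
  stopifnot(length(positions) == ncol(mat), nrow(mat) == length(taxa),
            !is.unsorted(positions, strictly = TRUE) || length(positions) < 2)
  structure(list(positions = as.numeric(positions), mat = mat,
                 taxa = as.character(taxa),
                 locus_length = as.numeric(locus_length)),
            class = "haplotype_sample")
}

#' @export
print.haplotype_sample <- function(x, ...) {
  cat(sprintf("Haplotype sample: %d haplotypes (%s), %d segregating sites, locus %g bp\n",
              nrow(x$mat),
              paste(sprintf("%s=%d", names(table(x$taxa)), table(x$taxa)),
                    collapse = ", "),
              ncol(x$mat), x$locus_length))
  invisible(x)
}

#' Simulate one locus end to end (genealogy + mutations)
#'
#' @inheritParams two_phase_genealogy
#' @param theta see [overlay_mutations()].
#' @return a `haplotype_sample`.
#' @export
simulate_locus <- function(model, locus_length,
                           sample_sizes = c(n_R = 46, n_I = 22, n_J = 21),
                           theta = NULL, seed = NULL) {
  local_seed(seed)
  g <- two_phase_genealogy(model, locus_length, sample_sizes)
  overlay_mutations(g, theta)
}

#' Simulate a multi-locus three-taxon dataset
#'
#' Loci are independent draws from the same history (independent chromosomes
#' or well-separated regions).
#'
#' @inheritParams simulate_locus
#' @param n_loci number of loci.
#' @return list of `haplotype_sample` objects, length `n_loci`.
#' @export
simulate_three_taxon_genome <- function(model, n_loci, locus_length,
                                        sample_sizes = c(n_R = 46, n_I = 22,
                                                         n_J = 21),
                                        theta = NULL, seed = NULL) {
  stopifnot(n_loci >= 1)
  local_seed(seed)
  lapply(seq_len(n_loci), function(i)
    simulate_locus(model, locus_length, sample_sizes, theta))
}

#' Write a haplotype sample as ms-style text
#'
#' Emits the conventional `segsites:` / `positions:` / 0-1 row block used by
#' Hudson's ms, for interoperability with downstream summary tools. Positions
#' are scaled to (0, 1).
#'
#' @param sample a `haplotype_sample`.
#' @param path output file path or connection.
#' @return `path`, invisibly.
#' @export
write_ms <- function(sample, path) {
  stopifnot(inherits(sample, "haplotype_sample"))
  con <- if (is.character(path)) file(path, "w") else path
  if (is.character(path)) on.exit(close(con))
  writeLines("//", con)
  writeLines(sprintf("segsites: %d", ncol(sample$mat)), con)
  if (ncol(sample$mat) > 0) {
    writeLines(paste("positions:",
                     paste(sprintf("%.6f", sample$positions / sample$locus_length),
                           collapse = " ")), con)
    writeLines(apply(sample$mat, 1, paste, collapse = ""), con)
  }
  invisible(path)
}
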
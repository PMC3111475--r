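#' Demographic model for a three-taxon domestication history
#'
#' Describes the genealogical history of a wild progenitor (R) and two
#' domesticated taxa (I and J) under one of two topologies:
#'
#' * `"independent"`: I and J were each domesticated directly from R at time
#'   `T_d`, giving a trifurcating history (branch widths = `N_I`, `N_R`,
#'   `N_J`).
#' * `"sequential"`: I and J share a common domesticated stem that split from
#'   R at time `T_d_prime`; I and J diverged from each other at `T_split`
#'   (< `T_d_prime`), so the two cultivars are most closely related to each
#'   other.
#'
#' Times are in units of `4 * N_R` generations and the scaled mutation rate is
#' `mut_rate_theta = 4 * N_R * mu` per site (ms convention). Population sizes
#' may be given on any absolute scale; only the ratios `N_I / N_R` etc. enter
#' the coalescent.
#'
#' Both cultivars are selfers: after domestication the effective recombination
#' rate on the cultivar branches is `recomb_rate * (1 - selfing_rate)`, zero at
#' the default `selfing_rate = 1`, so the whole locus shares a single
#' genealogy from the present back to the domestication time. In the wild
#' (ancestral) phase recombination is free; the locus is partitioned into
#' non-recombining sub-segments with geometric breakpoints at rate
#' `2 * 4 * N_R * recomb_rate` per bp (roughly one breakpoint per expected
#' crossover on a lineage pair of O(1) coalescent depth).
#'
#' @param topology `"independent"` or `"sequential"`.
#' @param N_R,N_I,N_J effective population sizes (diploid-equivalent; only
#'   ratios to `N_R` matter).
#' @param T time of the most recent common ancestor of the three taxa, in
#'   `4 N_R` generations; used only to validate that domestication is more
#'   recent than the deepest history.
#' @param T_d domestication time for the independent topology.
#' @param T_d_prime shared domestication time for the sequential topology.
#' @param T_split I/J divergence time under the sequential topology; defaults
#'   to `T_d_prime / 2`.
#' @param N_D size of the shared domesticated stem (sequential topology);
#'   defaults to `N_I + N_J`.
#' @param selfing_rate fraction of selfing after domestication, in \[0, 1\].
#' @param recomb_rate per-site per-generation recombination probability in the
#'   wild phase.
#' @param mut_rate_theta scaled per-site mutation rate `4 N_R mu`.
#' @return an object of class `demographic_model`.
#' @examples
#' m <- demographic_model("independent", N_R = 1e5, N_I = 3e4, N_J = 5e3,
#'                        T = 5, T_d = 0.025)
#' m
#' @export
demographic_model <- function(topology = c("independent", "sequential"),
                              N_R = 1e5, N_I = 0.6 * N_R, N_J = 0.04 * N_R,
                              T = 5, T_d = 0.025, T_d_prime = 0.025,
                              T_split = T_d_prime / 2, N_D = N_I + N_J,
                              selfing_rate = 1,
                              recomb_rate = 2.5e-9,
                              mut_rate_theta = 0.004) {
  topology <- match.arg(topology)
  stopifnot(N_R > 0, N_I > 0, N_J > 0, N_D > 0,
            selfing_rate >= 0, selfing_rate <= 1,
            recomb_rate >= 0, mut_rate_theta >= 0, T > 0)
  if (topology == "independent") {
    if (!(T_d > 0 && T_d < T)) stop("need 0 < T_d < T")
  } else {
    if (!(T_d_prime > 0 && T_d_prime < T)) stop("need 0 < T_d_prime < T")
    if (!(T_split > 0 && T_split < T_d_prime))
      stop("need 0 < T_split < T_d_prime")
  }
  structure(list(topology = topology, N_R = N_R, N_I = N_I, N_J = N_J,
                 N_D = N_D, T = T, T_d = T_d, T_d_prime = T_d_prime,
                 T_split = T_split, selfing_rate = selfing_rate,
                 recomb_rate = recomb_rate, mut_rate_theta = mut_rate_theta),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model (", x$topology, " domestication)\n", sep = "")
  cat(sprintf("  N_R = %g, N_I = %g, N_J = %g (ratios %.3g / %.3g)\n",
              x$N_R, x$N_I, x$N_J, x$N_I / x$N_R, x$N_J / x$N_R))
  if (x$topology == "independent") {
    cat(sprintf("  T_d = %g, T = %g (units of 4 N_R generations)\n",
                x$T_d, x$T))
  } else {
    cat(sprintf("  T_split = %g, T_d' = %g, T = %g (units of 4 N_R gen.), N_D = %g\n",
                x$T_split, x$T_d_prime, x$T, x$N_D))
  }
  cat(sprintf("  selfing = %g, recomb = %g /site/gen, theta = %g /site\n",
              x$selfing_rate, x$recomb_rate, x$mut_rate_theta))
  invisible(x)
}

# domestication time actually used by the simulator
model_T_dom <- function(model) {
  if (model$topology == "independent") model$T_d else model$T_d_prime
}

# wild-phase breakpoint rate per bp (geometric sub-segment partition)
model_breakpoint_rate <- function(model) {
  2 * 4 * model$N_R * model$recomb_rate
}

#' Read or write a demographic model as YAML
#'
#' The file carries a `demography:` block whose keys mirror the
#' [demographic_model()] fields, for interoperable pipeline configs.
#'
#' @param path file path.
#' @param model a `demographic_model`.
#' @return `read_demography_yaml` returns a `demographic_model`;
#'   `write_demography_yaml` returns `path` invisibly.
#' @export
read_demography_yaml <- function(path) {
  conf <- yaml::read_yaml(path)
  dem <- conf$demography %||% conf
  do.call(demographic_model, dem)
}

#' @rdname read_demography_yaml
#' @export
write_demography_yaml <- function(model, path) {
  stopifnot(inherits(model, "demographic_model"))
  yaml::write_yaml(list(demography = unclass(model)), path)
  invisible(path)
}
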
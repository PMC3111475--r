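#' Call segregating sites from dual-platform pooled counts
#'
#' A site is callable iff its read depth is at least `min_coverage` on BOTH
#' platforms. Among callable sites, the majority allele is the most frequent
#' allele in the combined (platform 1 + platform 2) counts and the focal
#' variant is the most frequent non-majority allele; other alleles are
#' ignored. The site-selection schemes are:
#'
#' * `"s"` -- the focal variant has count >= 1 on both platforms (all
#'   polymorphic sites seen by both methods);
#' * `"s_gt1"` -- count >= 2 on both platforms (singletons discarded; the
#'   scheme used for all diversity scans);
#' * `"s_gt2"` -- count >= 3 on both platforms (doubletons discarded too).
#'
#' Requiring the variant on both platforms suppresses platform-specific
#' sequencing errors, which inflate single-platform all-sites counts through
#' excess singletons and doubletons.
#'
#' @param counts_platform1,counts_platform2 `L x 4` integer allele-count
#'   matrices for the two platforms, or a single `pool_counts` object as
#'   `counts_platform1` (then `counts_platform2` is ignored).
#' @param min_coverage minimum per-platform depth for a callable site.
#' @param scheme site-selection scheme, see above.
#' @return object of class `seg_sites` with per-site logical/integer vectors
#'   (`callable`, `is_S`, `is_S_gt1`, `is_S_gt2`, per-platform depths and
#'   focal-variant counts, per-platform "any non-majority allele" counts) and
#'   totals `L` (callable sites), `S`, `S_gt1`, `S_gt2`, `S_single` (per
#'   platform, all-sites rule).
#' @export
call_segregating_sites <- function(counts_platform1, counts_platform2 = NULL,
                                   min_coverage = 6,
                                   scheme = c("s_gt1", "s", "s_gt2")) {
  scheme <- match.arg(scheme)
  if (inherits(counts_platform1, "pool_counts")) {
    pc <- counts_platform1
    counts_platform1 <- pc$counts[[1]]
    counts_platform2 <- pc$counts[[2]]
  }
  m1 <- as.matrix(counts_platform1); m2 <- as.matrix(counts_platform2)
  if (!all(dim(m1) == dim(m2)))
    stop("platform count tables must cover the same coordinate space")
  if (nrow(m1) == 0) stop("empty input")
  stopifnot(min_coverage >= 1)
  L_tot <- nrow(m1)
  depth1 <- rowSums(m1); depth2 <- rowSums(m2)
  callable <- depth1 >= min_coverage & depth2 >= min_coverage
  comb <- m1 + m2
  maj <- max.col(comb, ties.method = "first")
  idx <- cbind(seq_len(L_tot), maj)
  comb_nomaj <- comb
  comb_nomaj[idx] <- -1L
  focal <- max.col(comb_nomaj, ties.method = "first")
  fidx <- cbind(seq_len(L_tot), focal)
  var1 <- m1[fidx]; var2 <- m2[fidx]
  has_var <- comb[fidx] > 0
  nonmaj1 <- depth1 - m1[idx]   # any non-majority allele, per platform
  nonmaj2 <- depth2 - m2[idx]
  is_S <- callable & has_var & var1 >= 1 & var2 >= 1
  is_S_gt1 <- callable & var1 >= 2 & var2 >= 2
  is_S_gt2 <- callable & var1 >= 3 & var2 >= 3
  structure(list(
    callable = callable, depth1 = depth1, depth2 = depth2,
    var1 = var1, var2 = var2, nonmaj1 = nonmaj1, nonmaj2 = nonmaj2,
    is_S = is_S, is_S_gt1 = is_S_gt1, is_S_gt2 = is_S_gt2,
    L = sum(callable), S = sum(is_S), S_gt1 = sum(is_S_gt1),
    S_gt2 = sum(is_S_gt2),
    S_single = c(sum(callable & nonmaj1 >= 1), sum(callable & nonmaj2 >= 1)),
    S_gt2_single = c(sum(callable & var1 >= 3 & has_var),
                     sum(callable & var2 >= 3 & has_var)),
    min_coverage = min_coverage, scheme = scheme), class = "seg_sites")
}

#' @export
print.seg_sites <- function(x, ...) {
  cat(sprintf("Segregating sites: L = %d callable (>=%dX both platforms), S = %d, S_>1 = %d, S_>2 = %d\n",
              x$L, x$min_coverage, x$S, x$S_gt1, x$S_gt2))
  invisible(x)
}

#' Watterson estimator of theta per kb
#'
#' `theta = 1000 * S / (a_n * L)` with `a_n = 1 + 1/2 + ... + 1/(n-1)`, the
#' expectation normaliser `E(S) = a_n * theta`. `n` is the number of haploid
#' lineages sampled (one per selfing cultivar accession, two per outcrossing
#' wild accession).
#'
#' @param S_count number(s) of segregating sites.
#' @param n haploid sample size (>= 2).
#' @param L number of callable sites (>= 1); same length as `S_count` or 1.
#' @return theta per kb (vectorised over `S_count` / `L`).
#' @examples
#' watterson_theta(5, n = 2, L = 1000)   # a_2 = 1 -> 5 per kb
#' @export
watterson_theta <- function(S_count, n, L) {
  if (n < 2) stop("n must be >= 2")
  if (any(L <= 0)) stop("L must be positive")
  1000 * S_count / (a_n(n) * L)
}

#' Sliding-window diversity
#'
#' Slides a `window`-bp window in `step`-bp increments along the region and
#' estimates Watterson theta per kb in every window with at least
#' `min_callable` sites covered by `min_read_depth`+ reads on both platforms;
#' windows below that coverage, and windows extending past the region end,
#' are not emitted. Theta uses the window's segregating count under `scheme`
#' and its callable length (so estimates are robust to coverage gaps).
#'
#' @param site_set a `seg_sites` object (carries per-site depths).
#' @param n haploid sample size.
#' @param window,step window and step sizes in bp; `step` must divide
#'   `window`.
#' @param min_callable minimum callable sites per emitted window.
#' @param min_read_depth per-platform depth for window callability.
#' @param scheme segregating-site scheme for the window counts.
#' @param chrom chromosome label for the output.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `theta_per_kb`, `n_callable`.
#' @export
sliding_window_theta <- function(site_set, n, window = 100000, step = 10000,
                                 min_callable = 10000, min_read_depth = 4,
                                 scheme = c("s_gt1", "s", "s_gt2"),
                                 chrom = "chr1") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(site_set, "seg_sites"))
  if (window < step) stop("window must be >= step")
  if (window %% step != 0) stop("step must divide window")
  if (min_callable < 0 || min_read_depth < 0) stop("negative threshold")
  L_tot <- length(site_set$depth1)
  callable <- site_set$depth1 >= min_read_depth &
              site_set$depth2 >= min_read_depth
  k <- switch(scheme, s = 1L, s_gt1 = 2L, s_gt2 = 3L)
  seg <- callable & site_set$var1 >= k & site_set$var2 >= k &
         (site_set$var1 + site_set$var2) > 0
  if (L_tot < window)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), theta_per_kb = numeric(),
                      n_callable = integer()))
  starts <- seq(0L, L_tot - window, by = step)
  cc <- c(0, cumsum(callable))
  cs <- c(0, cumsum(seg))
  n_call <- cc[starts + window + 1L] - cc[starts + 1L]
  n_seg <- cs[starts + window + 1L] - cs[starts + 1L]
  keep <- n_call >= min_callable
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = starts[keep] + window,
             theta_per_kb = watterson_theta(n_seg[keep], n,
                                            pmax(n_call[keep], 1L)),
             n_callable = n_call[keep])
}

#' Median-of-windows diversity calls for 10 kb regions
#'
#' Each `step`-bp tile is assigned the median theta of all emitted windows
#' covering it (most tiles are covered by `window/step` windows); tiles
#' covered by fewer than `min_windows` emitted windows are dropped. A tile is
#' flagged low iff its median is strictly below `cutoff`; the median of an
#' even number of windows is the mean of the two central values.
#'
#' @param windows data.frame from [sliding_window_theta()].
#' @param cutoff low-diversity cutoff (theta per kb), e.g. from
#'   [shuffle_cutoff()]; `NA` leaves the `low` flag `NA`.
#' @param window,step sizes used for the windows, in bp.
#' @param min_windows minimum covering windows for a retained tile.
#' @return data.frame with `chrom`, `start`, `end`, `median_theta`,
#'   `n_windows`, `low`.
#' @export
region_median_theta <- function(windows, cutoff = NA, window = 100000,
                                step = 10000, min_windows = 4) {
  stopifnot(is.na(cutoff) || cutoff >= 0)
  if (nrow(windows) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), median_theta = numeric(),
                      n_windows = integer(), low = logical()))
  per <- as.integer(window / step)
  # expand each window over the tiles it covers
  exp <- data.table::data.table(
    chrom = rep(windows$chrom, each = per),
    tile = rep(windows$start, each = per) +
           rep(step * (seq_len(per) - 1L), times = nrow(windows)),
    theta_per_kb = rep(as.numeric(windows$theta_per_kb), each = per))
  agg <- exp[, list(median_theta = stats::median(theta_per_kb),
                    n_windows = .N), by = c("chrom", "tile")]
  agg <- agg[agg$n_windows >= min_windows, ]
  agg <- agg[order(agg$chrom, agg$tile), ]
  data.frame(chrom = agg$chrom, start = agg$tile, end = agg$tile + step,
             median_theta = agg$median_theta, n_windows = agg$n_windows,
             low = if (is.na(cutoff)) NA else agg$median_theta < cutoff)
}
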
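#' Per-unit segregating and callable counts ("callable genome")
#'
#' Summarises a `seg_sites` object into fixed-size units (default 1 kb): per
#' unit, the number of segregating sites under `scheme` and the number of
#' callable sites at the window depth rule. This unit table is the input to
#' the genome-shuffle cutoff calibration; shuffling permutes whole units, so
#' the unit totals are sufficient statistics for every shuffled window.
#'
#' @param site_set a `seg_sites` object (one chromosome/region).
#' @param unit unit size in bp.
#' @param min_read_depth per-platform depth for callability (window rule).
#' @param scheme segregating-site scheme.
#' @param chrom chromosome label.
#' @return data.frame with `chrom`, `start`, `S`, `callable` (one row per
#'   complete unit; a trailing partial unit is dropped).
#' @export
genome_units <- function(site_set, unit = 1000, min_read_depth = 4,
                         scheme = c("s_gt1", "s", "s_gt2"), chrom = "chr1") {
  scheme <- match.arg(scheme)
  stopifnot(inherits(site_set, "seg_sites"), unit >= 1)
  L_tot <- length(site_set$depth1)
  n_units <- L_tot %/% unit
  if (n_units == 0) stop("region shorter than one unit")
  callable <- site_set$depth1 >= min_read_depth &
              site_set$depth2 >= min_read_depth
  k <- switch(scheme, s = 1L, s_gt1 = 2L, s_gt2 = 3L)
  seg <- callable & site_set$var1 >= k & site_set$var2 >= k &
         (site_set$var1 + site_set$var2) > 0
  grp <- rep(seq_len(n_units), each = unit)
  use <- seq_len(n_units * unit)
  data.frame(chrom = chrom, start = (seq_len(n_units) - 1L) * unit,
             S = as.integer(rowsum(as.integer(seg[use]), grp)),
             callable = as.integer(rowsum(as.integer(callable[use]), grp)))
}

#' Shuffle-calibrated low-diversity cutoff
#'
#' Breaks the callable genome into fixed-size units (rows of `units`),
#' randomly permutes them `n_shuffles` times (genome-wide by default, so
#' local diversity structure is destroyed and adjacent segments become
#' independent), re-cuts each permutation into the original chromosome
#' lengths, estimates theta in non-overlapping `window`-bp windows, and
#' records the minimum window theta (`theta_min`) of each shuffle. The cutoff
#' is the `rank`-th smallest of the `n_shuffles` minima, so a fresh
#' homogeneous genome has probability about `rank / n_shuffles` of showing
#' any window at or below the cutoff (with `n_shuffles = 200` and
#' `rank = 10`, an empirical significance of 0.05).
#'
#' @param units unit table from [genome_units()] (columns `chrom`, `start`,
#'   `S`, `callable`), or a list of such tables (one per chromosome), rbound.
#' @param n haploid sample size for the Watterson estimator.
#' @param unit unit size in bp (must divide `window`).
#' @param n_shuffles number of random shuffles.
#' @param rank order statistic of the theta_min list used as the cutoff.
#' @param window window size in bp.
#' @param min_callable minimum callable sites for a window to enter the
#'   minimum (same rule as the real scan).
#' @param per_chromosome if `TRUE`, shuffle units within each chromosome
#'   instead of genome-wide.
#' @param seed optional integer seed.
#' @return object of class `shuffle_cutoff`: list with `theta_min`
#'   (length `n_shuffles`), `cutoff`, `n_shuffles`, `rank` and
#'   `significance = rank / n_shuffles`.
#' @export
shuffle_cutoff <- function(units, n, unit = 1000, n_shuffles = 200,
                           rank = 10, window = 100000, min_callable = 10000,
                           per_chromosome = FALSE, seed = NULL) {
  if (is.list(units) && !is.data.frame(units))
    units <- do.call(rbind, units)
  stopifnot(all(c("chrom", "S", "callable") %in% names(units)),
            window %% unit == 0)
  if (rank > n_shuffles) stop("rank must be <= n_shuffles")
  n_units <- nrow(units)
  per_win <- window %/% unit
  if (n_units < per_win) stop("genome shorter than one window")
  local_seed(seed)
  # fixed window layout over genome slots: windows never span chromosomes
  chrom_sizes <- table(factor(units$chrom, levels = unique(units$chrom)))
  win_id <- unlist(lapply(chrom_sizes, function(m) {
    nw <- m %/% per_win
    c(rep(seq_len(nw), each = per_win), rep(NA_integer_, m - nw * per_win))
  }), use.names = FALSE)
  # windows numbered globally
  offs <- cumsum(c(0, vapply(chrom_sizes, function(m) m %/% per_win, 0)))
  win_id <- win_id + rep(offs[-length(offs)], chrom_sizes)
  ok <- !is.na(win_id)
  an <- a_n(n)
  chrom_grp <- if (per_chromosome) factor(units$chrom, unique(units$chrom))
               else NULL
  theta_min <- vapply(seq_len(n_shuffles), function(i) {
    perm <- if (is.null(chrom_grp)) sample.int(n_units) else {
      idx <- seq_len(n_units)
      unlist(lapply(split(idx, chrom_grp), sample), use.names = FALSE)
    }
    Sw <- rowsum(units$S[perm][ok], win_id[ok])
    Cw <- rowsum(units$callable[perm][ok], win_id[ok])
    keep <- Cw >= min_callable
    if (!any(keep)) return(NA_real_)
    min(1000 * Sw[keep] / (an * Cw[keep]))
  }, numeric(1))
  if (anyNA(theta_min)) stop("some shuffles had no callable window")
  structure(list(theta_min = theta_min, cutoff = sort(theta_min)[rank],
                 n_shuffles = n_shuffles, rank = rank,
                 significance = rank / n_shuffles,
                 window = window, unit = unit), class = "shuffle_cutoff")
}

#' @export
print.shuffle_cutoff <- function(x, ...) {
  cat(sprintf("Shuffle cutoff: %.4g theta/kb (rank %d of %d shuffles, P = %.3g)\n",
              x$cutoff, x$rank, x$n_shuffles, x$significance))
  invisible(x)
}

#' Write a shuffle-cutoff report as YAML
#'
#' @param x a `shuffle_cutoff`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cutoff_yaml <- function(x, path) {
  stopifnot(inherits(x, "shuffle_cutoff"))
  yaml::write_yaml(list(cutoff = x$cutoff, rank = x$rank,
                        n_shuffles = x$n_shuffles,
                        significance = x$significance,
                        theta_min = x$theta_min), path)
  invisible(path)
}

ldr_size_bins <- c(0, 1e5, 2e5, 3e5, 4e5, 5e5, 6e5, Inf)
ldr_size_labels <- c("<100", "100-200", "200-300", "300-400", "400-500",
                     "500-600", ">=600")

#' Merge low tiles into low-diversity-region contigs
#'
#' Maximal runs of adjacent low tiles (from [region_median_theta()]) are
#' merged into LDR contigs. Tiles that were dropped by the covering-window
#' rule break runs (a contig cannot bridge an uncalled tile), and contigs
#' never span chromosomes. Sizes are classified into left-closed kb bins
#' (`<100`, `100-200`, ..., `>=600`).
#'
#' @param region_calls data.frame from [region_median_theta()].
#' @param cutoff low-diversity cutoff (theta per kb); a tile is low iff its
#'   median theta is strictly below it. If `NA`, the existing `low` column is
#'   used.
#' @param taxon optional taxon label carried through to the output.
#' @return data.frame with `taxon`, `chrom`, `start`, `end`, `size`,
#'   `size_class`.
#' @export
detect_ldr_contigs <- function(region_calls, cutoff = NA, taxon = NA) {
  rc <- region_calls
  low <- if (is.na(cutoff)) rc$low else rc$median_theta < cutoff
  rc <- rc[low, , drop = FALSE]
  if (nrow(rc) == 0)
    return(data.frame(taxon = character(), chrom = character(),
                      start = numeric(), end = numeric(), size = numeric(),
                      size_class = character()))
  rc <- rc[order(rc$chrom, rc$start), ]
  new_run <- c(TRUE, rc$chrom[-1] != rc$chrom[-nrow(rc)] |
                     rc$start[-1] != rc$end[-nrow(rc)])
  run <- cumsum(new_run)
  start <- tapply(rc$start, run, min)
  end <- tapply(rc$end, run, max)
  chrom <- tapply(as.character(rc$chrom), run, `[`, 1)
  size <- end - start
  data.frame(taxon = taxon, chrom = as.character(chrom),
             start = as.numeric(start), end = as.numeric(end),
             size = as.numeric(size),
             size_class = as.character(cut(as.numeric(size),
                                           breaks = ldr_size_bins,
                                           labels = ldr_size_labels,
                                           right = FALSE)),
             row.names = NULL)
}

#' Tabulate LDR contigs by size class
#'
#' Counts contigs in the kb size bins (`<100`, `100-200`, ..., `>=600`; bins
#' are left-closed, so a 200,000 bp contig falls in `200-300`) and reports
#' the fraction of the genome covered by contigs below and at/above 200 kb.
#'
#' @param contigs data.frame from [detect_ldr_contigs()].
#' @param genome_size total genome size in bp (> 0).
#' @return list with `counts` (named integer vector per bin),
#'   `pct_genome_lt_200k`, `pct_genome_ge_200k` (percent of genome).
#' @export
size_classify <- function(contigs, genome_size) {
  stopifnot(genome_size > 0)
  counts <- table(factor(contigs$size_class, levels = ldr_size_labels))
  lt <- contigs$size < 2e5
  list(counts = setNames(as.integer(counts), ldr_size_labels),
       pct_genome_lt_200k = 100 * sum(contigs$size[lt]) / genome_size,
       pct_genome_ge_200k = 100 * sum(contigs$size[!lt]) / genome_size)
}

#' Overlapping LDRs between two taxa
#'
#' Intersects the LDR contigs of two taxa per chromosome; adjacent or
#' overlapping pieces of the intersection are merged and empty intersections
#' are omitted. The result is symmetric in its arguments and covered by both
#' inputs.
#'
#' @param contigs_a,contigs_b contig tables from [detect_ldr_contigs()].
#' @return data.frame with `chrom`, `start`, `end`, `size`, `size_class`.
#' @export
overlap_ldrs <- function(contigs_a, contigs_b) {
  lev <- union(unique(contigs_a$chrom), unique(contigs_b$chrom))
  mk <- function(x) GenomicRanges::GRanges(
    factor(x$chrom, levels = lev),
    IRanges::IRanges(start = x$start + 1, end = x$end))
  if (nrow(contigs_a) == 0 || nrow(contigs_b) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), size = numeric(),
                      size_class = character()))
  ov <- GenomicRanges::reduce(GenomicRanges::intersect(mk(contigs_a),
                                                       mk(contigs_b)))
  if (length(ov) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), size = numeric(),
                      size_class = character()))
  size <- BiocGenerics::width(ov)
  data.frame(chrom = as.character(GenomicRanges::seqnames(ov)),
             start = BiocGenerics::start(ov) - 1,
             end = BiocGenerics::end(ov), size = size,
             size_class = as.character(cut(size, breaks = ldr_size_bins,
                                           labels = ldr_size_labels,
                                           right = FALSE)))
}

#' Lowest-diversity fraction of region calls
#'
#' Returns the retained tiles with the smallest median theta totalling the
#' given fraction of all retained tiles (ties at the boundary broken by
#' chromosome, then start coordinate).
#'
#' @param region_calls data.frame from [region_median_theta()].
#' @param fraction fraction of tiles to keep, in (0, 1].
#' @return subset of `region_calls`.
#' @export
bottom_fraction_ldrs <- function(region_calls, fraction = 0.05) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  n <- nrow(region_calls)
  if (n == 0) return(region_calls)
  k <- ceiling(fraction * n - 1e-9)
  ord <- order(region_calls$median_theta, region_calls$chrom,
               region_calls$start)
  region_calls[sort(ord[seq_len(k)]), , drop = FALSE]
}

#' Write intervals as BED
#'
#' 0-based half-open coordinates, tab-separated, no header.
#'
#' @param x data.frame with `chrom`, `start`, `end` (extra columns appended).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end",
            setdiff(names(x), c("chrom", "start", "end")))
  write.table(x[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
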
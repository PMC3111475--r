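#' Emulate pooled two-platform sequencing of a haplotype sample
#'
#' For each taxon in the sample and each of two sequencing platforms, read
#' depth at every site is Poisson(`mean_coverage`), each read is drawn from
#' the taxon pool's haplotype frequencies, and each read base is substituted
#' independently with the platform's error rate (uniformly to one of the
#' three other alleles). Platform errors are independent -- the property the
#' combined-platform segregating-site filter exploits.
#'
#' Alleles are kept in site-local coding: slot 1 = ancestral/reference allele,
#' slot 2 = the derived variant (if the site segregates in the sample),
#' slots 3-4 = the two remaining (error-only) alleles.
#'
#' Segregating-site positions are floored to integer bp; the rare collisions
#' (two infinite-sites mutations in one bp) are shifted to the nearest free
#' base.
#'
#' @param sample a `haplotype_sample`.
#' @param mean_coverage mean per-platform read depth (> 0).
#' @param error_rates length-2 vector of per-read-base substitution error
#'   rates, one per platform, each in \[0, 1).
#' @param seed optional integer seed.
#' @return named list (one element per taxon) of `pool_counts` objects: each
#'   has `taxon`, `L` (locus length in bp), and `counts`, a list of two
#'   `L x 4` integer matrices of per-site allele read counts (platforms 1
#'   and 2). The attribute `variant_pos` gives the 0-based integer positions
#'   of the sample's true segregating sites.
#' @export
simulate_pooled_platform_reads <- function(sample, mean_coverage = 30,
                                           error_rates = c(0.005, 0.005),
                                           seed = NULL) {
  stopifnot(inherits(sample, "haplotype_sample"), mean_coverage > 0,
            length(error_rates) == 2, all(error_rates >= 0),
            all(error_rates < 1))
  local_seed(seed)
  L <- as.integer(sample$locus_length)
  vpos <- snap_positions(floor(sample$positions), L)
  taxa <- unique(sample$taxa)
  out <- lapply(taxa, function(tx) {
    rows <- sample$taxa == tx
    freq <- if (ncol(sample$mat)) colMeans(sample$mat[rows, , drop = FALSE])
            else numeric(0)
    counts <- lapply(1:2, function(p)
      platform_counts(L, vpos, freq, mean_coverage, error_rates[p]))
    structure(list(taxon = tx, L = L, counts = counts,
                   mean_coverage = mean_coverage, error_rates = error_rates),
              class = "pool_counts", variant_pos = vpos)
  })
  names(out) <- taxa
  out
}

# resolve integer-position collisions by moving duplicates to the nearest
# free base
snap_positions <- function(ipos, L) {
  if (!anyDuplicated(ipos)) return(as.integer(ipos))
  occupied <- logical(L)
  occupied[ipos[!duplicated(ipos)] + 1L] <- TRUE
  for (i in which(duplicated(ipos))) {
    p <- ipos[i]
    for (d in seq_len(L)) {
      for (cand in c(p + d, p - d)) {
        if (cand >= 0 && cand < L && !occupied[cand + 1L]) {
          ipos[i] <- cand; occupied[cand + 1L] <- TRUE; d <- NA; break
        }
      }
      if (is.na(d)) break
    }
  }
  as.integer(ipos)
}

# one platform's L x 4 allele-count matrix for one taxon pool
platform_counts <- function(L, vpos, freq, cov, err) {
  depth <- rpois(L, cov)
  m <- matrix(0L, L, 4)
  alt_true <- integer(L)
  if (length(vpos))
    alt_true[vpos + 1L] <- rbinom(length(vpos), depth[vpos + 1L], freq)
  ref_true <- depth - alt_true
  if (err > 0) {
    ref_err <- rbinom(L, ref_true, err)       # ref reads mis-read
    alt_err <- rbinom(L, alt_true, err)       # variant reads mis-read
    # split errors uniformly among the three other alleles
    r1 <- rbinom(L, ref_err, 1 / 3)           # ref -> alt
    r2 <- rbinom(L, ref_err - r1, 1 / 2)      # ref -> o1
    r3 <- ref_err - r1 - r2                   # ref -> o2
    a1 <- rbinom(L, alt_err, 1 / 3)           # alt -> ref
    a2 <- rbinom(L, alt_err - a1, 1 / 2)      # alt -> o1
    a3 <- alt_err - a1 - a2                   # alt -> o2
    m[, 1] <- ref_true - ref_err + a1
    m[, 2] <- alt_true - alt_err + r1
    m[, 3] <- r2 + a2
    m[, 4] <- r3 + a3
  } else {
    m[, 1] <- ref_true
    m[, 2] <- alt_true
  }
  m
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("Pooled site counts: taxon %s, %d bp, 2 platforms, ~%gX, errors %s\n",
              x$taxon, x$L, x$mean_coverage,
              paste(x$error_rates, collapse = "/")))
  invisible(x)
}

#' Write / read per-site allele counts as tab-separated text
#'
#' Long format with columns `chrom`, `pos` (0-based), `taxon`, `platform`,
#' `allele`, `count`; zero counts are omitted. This is the interchange format
#' for user pipelines; the dense `pool_counts` object is used internally.
#'
#' @param pools named list of `pool_counts` (per taxon), as returned by
#'   [simulate_pooled_platform_reads()].
#' @param path output TSV path.
#' @param chrom chromosome name to write.
#' @return `path` invisibly; `read_site_counts` returns a `data.frame`.
#' @export
write_site_counts <- function(pools, path, chrom = "chr1") {
  rows <- lapply(pools, function(pc) {
    do.call(rbind, lapply(1:2, function(p) {
      m <- pc$counts[[p]]
      idx <- which(m > 0, arr.ind = TRUE)
      data.frame(chrom = chrom, pos = idx[, 1] - 1L, taxon = pc$taxon,
                 platform = p, allele = c("ref", "alt", "o1", "o2")[idx[, 2]],
                 count = m[idx])
    }))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$pos, df$taxon, df$platform), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Rebuild dense `pool_counts` objects from a long site-count table
#'
#' @param df data.frame as produced by [read_site_counts()].
#' @param L locus length in bp.
#' @return named list of `pool_counts` per taxon.
#' @export
pool_counts_from_table <- function(df, L) {
  allele_slot <- c(ref = 1L, alt = 2L, o1 = 3L, o2 = 4L)
  out <- lapply(split(df, df$taxon), function(dt) {
    counts <- lapply(1:2, function(p) {
      m <- matrix(0L, L, 4)
      dp <- dt[dt$platform == p, ]
      if (nrow(dp))
        m[cbind(dp$pos + 1L, allele_slot[dp$allele])] <- dp$count
      m
    })
    structure(list(taxon = dt$taxon[1], L = L, counts = counts,
                   mean_coverage = NA, error_rates = c(NA, NA)),
              class = "pool_counts")
  })
  out
}
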
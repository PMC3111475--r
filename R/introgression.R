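#' Describe a sweep-plus-introgression event
#'
#' Models a genomic segment that was selected (swept) in a donor taxon and
#' subsequently introgressed into a recipient taxon, so that within the region
#' both taxa descend from a single donor haplotype.
#'
#' @param donor,recipient taxon labels (e.g. `"I"`, `"J"`).
#' @param start,end half-open region bounds in bp within the locus.
#' @param time time since transfer in `4 N_R` generations; post-transfer
#'   mutations accumulate at rate `theta * time` per lineage.
#' @return object of class `introgression_event`.
#' @export
introgression_event <- function(donor, recipient, start, end, time = 0) {
  stopifnot(start >= 0, end > start, time >= 0, donor != recipient)
  structure(list(donor = donor, recipient = recipient,
                 start = start, end = end, time = time),
            class = "introgression_event")
}

#' Inject a shared sweep/introgression segment into a haplotype sample
#'
#' Within the event region, every recipient haplotype is replaced by a copy of
#' one randomly chosen donor haplotype. With `sweep_donor = TRUE` (default)
#' the donor haplotypes in the region are also replaced by that haplotype,
#' emulating a completed selective sweep in the donor followed by
#' introgression, so the region is a low-diversity region in both taxa and
#' the two cultivars are locally identical. Sites outside the region are
#' untouched. Optionally, post-transfer mutations are added on each affected
#' lineage as new singleton columns at rate `theta_site * region_length *
#' event$time` per haplotype.
#'
#' Columns rendered non-segregating by the replacement are dropped.
#'
#' @param sample a `haplotype_sample` containing donor and recipient taxa.
#' @param event an [introgression_event()]; region must lie within the locus.
#' @param sweep_donor replace donor haplotypes in the region too (see above).
#' @param theta_site scaled mutation rate for post-transfer mutations; `NULL`
#'   (default) adds none unless `event$time > 0` and a rate is supplied.
#' @param seed optional integer seed.
#' @return the modified `haplotype_sample`.
#' @export
inject_sweep_introgression <- function(sample, event, sweep_donor = TRUE,
                                       theta_site = NULL, seed = NULL) {
  stopifnot(inherits(sample, "haplotype_sample"),
            inherits(event, "introgression_event"))
  if (event$start < 0 || event$end > sample$locus_length)
    stop("event region outside locus bounds")
  if (!event$donor %in% sample$taxa || !event$recipient %in% sample$taxa)
    stop("donor or recipient taxon absent from sample")
  local_seed(seed)
  in_region <- sample$positions >= event$start & sample$positions < event$end
  donor_rows <- which(sample$taxa == event$donor)
  recip_rows <- which(sample$taxa == event$recipient)
  chosen <- donor_rows[sample.int(length(donor_rows), 1L)]
  mat <- sample$mat
  template <- mat[chosen, in_region]
  affected <- recip_rows
  if (sweep_donor) affected <- c(affected, setdiff(donor_rows, chosen))
  mat[affected, in_region] <- rep(template, each = length(affected))
  pos <- sample$positions
  # post-transfer mutations: independent singletons on each affected lineage
  if (!is.null(theta_site) && event$time > 0) {
    rate <- theta_site * (event$end - event$start) * event$time
    lineages <- c(recip_rows, if (sweep_donor) donor_rows else chosen)
    n_new <- rpois(length(lineages), rate)
    if (sum(n_new) > 0) {
      new_pos <- stats::runif(sum(n_new), event$start, event$end)
      new_cols <- matrix(0L, nrow(mat), sum(n_new))
      new_cols[cbind(rep(lineages, n_new), seq_len(sum(n_new)))] <- 1L
      mat <- cbind(mat, new_cols)
      pos <- c(pos, new_pos)
      ord <- order(pos)
      pos <- pos[ord]
      mat <- mat[, ord, drop = FALSE]
    }
  }
  counts <- colSums(mat)
  seg <- counts > 0 & counts < nrow(mat)
  haplotype_sample(pos[seg], mat[, seg, drop = FALSE], sample$taxa,
                   sample$locus_length)
}

#' Plant a divergent site into a haplotype sample
#'
#' Adds (or overwrites) one column at `position` where every haplotype of the
#' taxa in `carriers` carries the derived allele and all others are
#' ancestral. Used to construct candidate-screen fixtures with a known
#' cultivar-differentiating site.
#'
#' @param sample a `haplotype_sample`.
#' @param position 0-based bp offset within the locus.
#' @param carriers taxon labels fixed for the derived allele.
#' @return the modified `haplotype_sample`.
#' @export
plant_divergent_site <- function(sample, position, carriers = c("I", "J")) {
  stopifnot(inherits(sample, "haplotype_sample"),
            position >= 0, position < sample$locus_length)
  col <- as.integer(sample$taxa %in% carriers)
  keep <- sample$positions != position
  pos <- c(sample$positions[keep], position)
  mat <- cbind(sample$mat[, keep, drop = FALSE], col)
  ord <- order(pos)
  haplotype_sample(pos[ord], mat[, ord, drop = FALSE], sample$taxa,
                   sample$locus_length)
}
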
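#' Watterson-estimator recovery on synthetic pools
#'
#' Simulates `n_loci` independent loci for a single constant-size population
#' of `n` haploid lineages at the given diversity, emulates pooled
#' two-platform sequencing, calls segregating sites with the dual-platform
#' filters, and returns per-locus Watterson estimates under the all-sites and
#' singleton-excluding schemes, together with the analytic expectation of the
#' singleton-excluding estimator: removing unpolarized singletons (derived
#' count 1 or n-1) leaves `E[theta_hat_gt1] = theta * (a_n - 1 - 1/(n-1)) /
#' a_n`.
#'
#' The default 100X per-platform coverage makes site-calling completeness
#' essentially 1, so the experiment isolates the estimators themselves;
#' error-model experiments use the 30X study design instead (see
#' [error_filter_experiment()]).
#'
#' @param n_loci number of loci.
#' @param locus_length locus length in bp.
#' @param n haploid sample size.
#' @param theta_kb true theta per kb.
#' @param coverage mean per-platform coverage.
#' @param error_rates per-platform error rates.
#' @param min_coverage callability threshold (both platforms).
#' @param seed optional integer seed.
#' Two flavours of each estimate are returned: read-based (through the
#' pooled-read emulation and the dual-platform variant-read filters) and
#' sample-based (allele classes counted directly on the haplotype sample, so
#' the singleton-excluding scheme removes exactly the derived-count 1 and
#' n-1 classes that the analytic expectation refers to). Variant-read
#' thresholds only approximate allele-class thresholds -- at high coverage a
#' singleton carrier contributes many reads -- so the analytic comparison
#' uses the sample-based values.
#'
#' @return list with per-locus vectors `theta_all`, `theta_gt1` (read-based),
#'   `theta_all_sample`, `theta_gt1_sample`, `theta_single_p1/p2`
#'   (single-platform all-sites rule), their means and standard errors, the
#'   true theta and `expected_gt1`.
#' @export
theta_recovery_experiment <- function(n_loci = 500, locus_length = 10000,
                                      n = 22, theta_kb = 4, coverage = 100,
                                      error_rates = c(0, 0),
                                      min_coverage = 6, seed = NULL) {
  local_seed(seed)
  model <- demographic_model("independent", mut_rate_theta = theta_kb / 1000)
  sizes <- c(n_R = n, n_I = 0, n_J = 0)   # one constant-size population
  theta_all <- theta_gt1 <- theta_s1 <- theta_s2 <- numeric(n_loci)
  theta_all_s <- theta_gt1_s <- numeric(n_loci)
  for (i in seq_len(n_loci)) {
    smp <- simulate_locus(model, locus_length, sizes)
    pools <- simulate_pooled_platform_reads(smp, coverage, error_rates)
    ss <- call_segregating_sites(pools$R, min_coverage = min_coverage)
    L <- max(ss$L, 1)
    theta_all[i] <- watterson_theta(ss$S, n, L)
    theta_gt1[i] <- watterson_theta(ss$S_gt1, n, L)
    theta_s1[i] <- watterson_theta(ss$S_single[1], n, L)
    theta_s2[i] <- watterson_theta(ss$S_single[2], n, L)
    cnt <- colSums(smp$mat)                    # sample allele classes
    theta_all_s[i] <- watterson_theta(sum(cnt > 0 & cnt < n), n,
                                      locus_length)
    theta_gt1_s[i] <- watterson_theta(sum(cnt > 1 & cnt < n - 1), n,
                                      locus_length)
  }
  an <- a_n(n)
  list(theta_all = theta_all, theta_gt1 = theta_gt1,
       theta_all_sample = theta_all_s, theta_gt1_sample = theta_gt1_s,
       theta_single_p1 = theta_s1, theta_single_p2 = theta_s2,
       mean_all = mean(theta_all), mean_gt1 = mean(theta_gt1),
       mean_all_sample = mean(theta_all_s),
       mean_gt1_sample = mean(theta_gt1_s),
       mean_single_p1 = mean(theta_s1), mean_single_p2 = mean(theta_s2),
       theta_true = theta_kb,
       expected_gt1 = theta_kb * (an - 1 - 1 / (n - 1)) / an,
       se_gt1 = sd(theta_gt1) / sqrt(n_loci),
       se_gt1_sample = sd(theta_gt1_s) / sqrt(n_loci),
       se_all = sd(theta_all) / sqrt(n_loci))
}

#' Platform-error robustness of the combined singleton-excluding filter
#'
#' Runs the recovery experiment twice at the study design (30X per
#' platform): once error-free and once with the given per-platform error
#' rates. Platform errors are independent, so spurious variants almost never
#' reach count 2 on both platforms: single-platform all-sites estimates
#' inflate strongly while the combined singleton-excluding estimate barely
#' moves.
#'
#' @inheritParams theta_recovery_experiment
#' @param error_rate per-read-base substitution rate applied to both
#'   platforms in the error run.
#' @return list with the two runs (`clean`, `noisy`), the single-platform
#'   inflation factors and the relative shift of the combined estimate.
#' @export
error_filter_experiment <- function(n_loci = 100, locus_length = 10000,
                                    n = 22, theta_kb = 4, coverage = 30,
                                    error_rate = 0.005, min_coverage = 6,
                                    seed = NULL) {
  local_seed(seed)
  clean <- theta_recovery_experiment(n_loci, locus_length, n, theta_kb,
                                     coverage, c(0, 0), min_coverage)
  noisy <- theta_recovery_experiment(n_loci, locus_length, n, theta_kb,
                                     coverage, c(error_rate, error_rate),
                                     min_coverage)
  list(clean = clean, noisy = noisy,
       inflation_p1 = noisy$mean_single_p1 / clean$mean_single_p1,
       inflation_p2 = noisy$mean_single_p2 / clean$mean_single_p2,
       gt1_rel_shift = abs(noisy$mean_gt1 - clean$mean_gt1) / clean$mean_gt1)
}

#' Simulate a two-history genome: single-history background plus introgressed
#' sweep loci
#'
#' Simulates `config$n_loci` loci under `model` (normally the independent
#' domestication history) and injects a completed sweep-plus-introgression
#' event (donor I, recipient J, whole locus) into `inject_loci`, giving those
#' loci the shared, recent genealogy of a segment selected in one cultivar
#' and introgressed into the other while the rest of the genome keeps the
#' background history.
#'
#' @param model a [demographic_model()].
#' @param config a [d_pipeline_config()].
#' @param n_inject number of injected loci.
#' @param inject_loci locus indices to inject; defaults to the first
#'   `n_inject`.
#' @param seed optional integer seed.
#' @return list with `genome` (list of `haplotype_sample`) and
#'   `injected` (indices).
#' @export
make_two_history_genome <- function(model, config = d_pipeline_config(),
                                    n_inject = 10, inject_loci = NULL,
                                    seed = NULL) {
  local_seed(seed)
  genome <- simulate_three_taxon_genome(model, config$n_loci,
                                        config$locus_length,
                                        config$sample_sizes)
  injected <- inject_loci %||% seq_len(n_inject)
  for (i in injected) {
    ev <- introgression_event("I", "J", 0, config$locus_length)
    genome[[i]] <- inject_sweep_introgression(genome[[i]], ev)
  }
  list(genome = genome, injected = injected)
}

#' Genetic-distance pattern of injected overlapping LDRs
#'
#' For each replicate two-history genome, computes the three pairwise mean
#' genetic distances inside the injected loci and in the background
#' (non-injected) loci. In injected loci the two cultivars share one recent
#' haplotype, so d(I, J) drops below both wild-cultivar distances; in the
#' background the two wild-cultivar distances stay approximately equal.
#'
#' @param model a [demographic_model()].
#' @param n_reps replicates.
#' @param config a [d_pipeline_config()].
#' @param n_inject injected loci per replicate.
#' @param seed optional integer seed.
#' @return list with per-replicate matrices of distances (`inside`,
#'   `background`; columns IJ/RI/RJ), the fraction of replicates where
#'   d(I,J) inside < min(d(R,I), d(R,J)) inside, and the mean relative
#'   difference of the background wild-cultivar distances.
#' @export
distance_pattern_experiment <- function(model, n_reps = 30,
                                        config = d_pipeline_config(n_loci = 80,
                                                                   locus_length = 2000),
                                        n_inject = 4, seed = NULL) {
  local_seed(seed)
  inside <- background <- matrix(NA_real_, n_reps, 3,
                                 dimnames = list(NULL, c("IJ", "RI", "RJ")))
  for (r in seq_len(n_reps)) {
    th <- make_two_history_genome(model, config, n_inject)
    recs <- genome_fst_records(th$genome)
    grp <- recs$locus %in% th$injected
    for (set in c(TRUE, FALSE)) {
      d <- recs[grp == set, ]
      m <- c(genetic_distance(d$p_I, d$p_J), genetic_distance(d$p_R, d$p_I),
             genetic_distance(d$p_R, d$p_J))
      if (set) inside[r, ] <- m else background[r, ] <- m
    }
  }
  frac <- mean(inside[, "IJ"] < pmin(inside[, "RI"], inside[, "RJ"]))
  bg_rel <- abs(background[, "RI"] - background[, "RJ"]) /
    ((background[, "RI"] + background[, "RJ"]) / 2)
  list(inside = inside, background = background,
       frac_IJ_smallest = frac,
       mean_background_rel_diff = mean(bg_rel),
       background_rel_diff = bg_rel)
}

#' End-to-end candidate-gene screen on planted introgression fixtures
#'
#' Per replicate: builds a synthetic annotated genome with one gene per
#' region, simulates three-taxon haplotypes per region, injects a completed
#' sweep-plus-introgression into `n_inject` regions and plants one
#' nonsynonymous cultivar-differentiating site in each injected gene
#' (both cultivars fixed for the alternative allele, wild taxon ancestral).
#' The full screen is then run: overlapping low-diversity designation
#' (lowest `ldr_fraction` of regions in BOTH cultivars), one-sided KS
#' significance per overlapping region, Fst-triplet + coding-effect
#' candidate screen. Recovery and false positives are scored against the
#' planted truth.
#'
#' @param model a [demographic_model()].
#' @param n_reps replicates.
#' @param n_regions regions (= genes) per replicate.
#' @param region_length region length in bp.
#' @param n_inject planted regions per replicate.
#' @param sample_sizes haploid sample sizes.
#' @param ldr_fraction per-taxon low-diversity designation fraction.
#' @param seed optional integer seed.
#' @return list with per-replicate data.frame `results` (columns
#'   `recovered`, `n_planted`, `false_positives`), and totals
#'   `recovery_rate`, `total_false_positives`.
#' @export
candidate_screen_experiment <- function(model, n_reps = 20, n_regions = 12,
                                        region_length = 5000, n_inject = 3,
                                        sample_sizes = c(n_R = 46, n_I = 22,
                                                         n_J = 21),
                                        ldr_fraction = 0.3, seed = NULL) {
  local_seed(seed)
  res <- data.frame(recovered = integer(n_reps), n_planted = n_inject,
                    false_positives = integer(n_reps))
  for (r in seq_len(n_reps)) {
    one <- candidate_screen_replicate(model, n_regions, region_length,
                                      n_inject, sample_sizes, ldr_fraction)
    res$recovered[r] <- one$recovered
    res$false_positives[r] <- one$false_positives
  }
  list(results = res,
       recovery_rate = sum(res$recovered) / (n_reps * n_inject),
       total_false_positives = sum(res$false_positives))
}

candidate_screen_replicate <- function(model, n_regions, region_length,
                                       n_inject, sample_sizes,
                                       ldr_fraction) {
  fx <- make_annotation_fixture(n_regions * region_length, n_regions,
                                gene_length = 900, layout = "tiled",
                                region_length = region_length)
  genome <- simulate_three_taxon_genome(model, n_regions, region_length,
                                        sample_sizes)
  planted <- sort(sample.int(n_regions, n_inject))
  planted_pos <- integer(n_inject)
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(planted)) {
    i <- planted[k]
    ev <- introgression_event("I", "J", 0, region_length)
    genome[[i]] <- inject_sweep_introgression(genome[[i]], ev)
    # plant one nonsynonymous divergent site inside the region's gene
    g0 <- fx$genes$start[i] - (i - 1) * region_length  # region-local
    repeat {
      codon <- sample.int(298, 1)                      # inside the ORF
      gpos <- fx$genes$start[i] + 3 * codon + sample.int(3, 1) - 1
      ref <- as.character(Biostrings::subseq(fx$genome[[1]], gpos + 1,
                                             gpos + 1))
      alts <- setdiff(bases, ref)
      eff <- vapply(alts, function(a)
        classify_coding_effect(gpos, a, fx$models, fx$genome), "")
      if (any(eff == "nonsynonymous")) {
        alt <- alts[eff == "nonsynonymous"][1]
        break
      }
    }
    genome[[i]] <- plant_divergent_site(genome[[i]],
                                        gpos - (i - 1) * region_length + 0.5)
    planted_pos[k] <- gpos
    attr(genome[[i]], "planted_alt") <- alt
  }
  # overlapping low-diversity designation: at or below the k-th smallest
  # per-taxon theta (all ties at the boundary value count as low, as with a
  # cutoff; the severely bottlenecked cultivar often has several zero loci)
  k <- ceiling(ldr_fraction * n_regions)
  low_at <- function(theta) theta <= sort(theta)[k]
  low_I <- low_at(locus_theta(genome, "I"))
  low_J <- low_at(locus_theta(genome, "J"))
  overlapping <- which(low_I & low_J)
  recs <- genome_fst_records(genome)
  # genomic coordinates + alt-base metadata for the screen
  recs$chrom <- "chr1"
  recs$pos_genome <- (recs$locus - 1) * region_length + floor(recs$pos)
  ref_at <- function(p) as.character(Biostrings::subseq(fx$genome[[1]],
                                                        p + 1, p + 1))
  recs$alt_base <- vapply(recs$pos_genome, function(p) {
    r <- ref_at(p); sample(setdiff(bases, r), 1)
  }, "")
  for (k in seq_along(planted))                     # planted alts are known
    recs$alt_base[recs$pos_genome == planted_pos[k]] <-
      attr(genome[[planted[k]]], "planted_alt")
  # one-sided KS significance of each overlapping region
  sig <- overlapping[vapply(overlapping, function(i)
    region_ks_test(recs[recs$locus == i, ])$significant, TRUE)]
  sig_regions <- data.frame(chrom = "chr1",
                            start = (sig - 1) * region_length,
                            end = sig * region_length)
  screen_recs <- data.frame(chrom = recs$chrom, pos = recs$pos_genome,
                            alt_base = recs$alt_base, fst_IJ = recs$fst_IJ,
                            fst_RI = recs$fst_RI, fst_RJ = recs$fst_RJ)
  cand <- screen_candidate_genes(sig_regions, screen_recs, fx$models,
                                 fx$genome)
  cand_region_idx <- if (nrow(cand)) sig[cand$region] else integer()
  list(recovered = sum(planted %in% cand_region_idx),
       false_positives = sum(!cand_region_idx %in% planted),
       candidates = cand, planted = planted, significant = sig)
}
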
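test_that("a constant genome yields a degenerate cutoff and no LDRs", {
  units <- data.frame(chrom = "chr1", start = (0:999) * 1000, S = 15L,
                      callable = 1000L)
  sc <- shuffle_cutoff(units, n = 22, n_shuffles = 50, rank = 5, seed = 1)
  const_theta <- 1000 * (100 * 15) / (harmonic_oracle(21) * 100 * 1000)
  expect_true(all(abs(sc$theta_min - const_theta) < 1e-12))
  expect_equal(sc$cutoff, const_theta)
  # zero tiles strictly below the cutoff -> zero LDRs
  rc <- data.frame(chrom = "chr1", start = (0:99) * 10000,
                   end = (1:100) * 10000, median_theta = const_theta,
                   n_windows = 10L)
  expect_identical(nrow(detect_ldr_contigs(rc, cutoff = sc$cutoff)), 0L)
})

test_that("the rank convention fixes the empirical significance", {
  units <- homogeneous_units(400)
  sc <- shuffle_cutoff(units, n = 22, n_shuffles = 200, rank = 10, seed = 2)
  expect_identical(sc$significance, 0.05)
  expect_equal(sc$cutoff, sort(sc$theta_min)[10])
  expect_error(shuffle_cutoff(units, n = 22, n_shuffles = 20, rank = 30),
               "rank")
})

test_that("shuffling is deterministic under a seed", {
  units <- homogeneous_units(300)
  s1 <- shuffle_cutoff(units, n = 22, n_shuffles = 30, rank = 3, seed = 7)
  s2 <- shuffle_cutoff(units, n = 22, n_shuffles = 30, rank = 3, seed = 7)
  expect_identical(s1$theta_min, s2$theta_min)
  s3 <- shuffle_cutoff(units, n = 22, n_shuffles = 30, rank = 3, seed = 8,
                       per_chromosome = TRUE)
  expect_s3_class(s3, "shuffle_cutoff")
})

test_that("the cutoff calibrates fresh replicates near rank/n_shuffles", {
  set.seed(3)
  units <- homogeneous_units(2000)
  sc <- shuffle_cutoff(units, n = 22, n_shuffles = 200, rank = 10, seed = 4)
  # fresh shuffle-style replicate genomes, via the independent oracle
  set.seed(5)
  reps <- replicate(200, shuffle_once_oracle(units, 22), simplify = FALSE)
  offending <- vapply(reps, function(th) sum(th <= sc$cutoff), integer(1))
  frac <- mean(offending >= 1)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  # when a replicate offends, only a handful of windows do
  expect_lte(max(offending), 4)
})

test_that("global theta is invariant under shuffling", {
  units <- homogeneous_units(500)
  sc <- shuffle_cutoff(units, n = 22, n_shuffles = 5, rank = 1, seed = 9)
  expect_s3_class(sc, "shuffle_cutoff")
  # the multiset of unit contributions is preserved: global S and callable
  # totals (hence global theta) are permutation-invariant by construction
  expect_equal(1000 * sum(units$S) / (harmonic_oracle(21) * sum(units$callable)),
               watterson_theta(sum(units$S), 22, sum(units$callable)))
})

test_that("adjacent low tiles merge into contigs that respect breaks", {
  rc <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(0, 10000, 30000, 40000, 0),
    end = c(10000, 20000, 40000, 50000, 10000),
    median_theta = c(0.1, 0.1, 0.1, 5, 0.1), n_windows = 10L)
  contigs <- detect_ldr_contigs(rc, cutoff = 1, taxon = "I")
  expect_identical(nrow(contigs), 3L)
  expect_equal(contigs$start, c(0, 30000, 0))
  expect_equal(contigs$end, c(20000, 40000, 10000))   # gap at 20k breaks
  expect_identical(unique(contigs$taxon), "I")
})

test_that("size classes follow the left-closed kb bins", {
  rc <- data.frame(chrom = "chr1", start = seq(0, 240000, by = 10000),
                   end = seq(10000, 250000, by = 10000),
                   median_theta = 0, n_windows = 10L)
  contigs <- detect_ldr_contigs(rc, cutoff = 1)
  expect_identical(contigs$size_class, "200-300")      # 250 kb contig
  cls <- size_classify(contigs, genome_size = 1e7)
  expect_identical(unname(cls$counts["200-300"]), 1L)
  expect_equal(cls$pct_genome_ge_200k, 2.5)
  expect_equal(cls$pct_genome_lt_200k, 0)
  # boundary: exactly 200,000 bp falls in the 200-300 bin
  b <- data.frame(taxon = NA, chrom = "chr1", start = 0, end = 2e5,
                  size = 2e5, size_class = NA)
  expect_identical(
    as.character(cut(b$size, c(0, 1e5, 2e5, 3e5, 4e5, 5e5, 6e5, Inf),
                     labels = c("<100", "100-200", "200-300", "300-400",
                                "400-500", "500-600", ">=600"),
                     right = FALSE)), "200-300")
  # bins partition all sizes
  sizes <- c(1, 99999, 100000, 199999, 200000, 599999, 600000, 5e6)
  bins <- cut(sizes, c(0, 1e5, 2e5, 3e5, 4e5, 5e5, 6e5, Inf), right = FALSE)
  expect_false(anyNA(bins))
  # empty input
  empty <- size_classify(detect_ldr_contigs(rc[0, ], cutoff = 1), 1e7)
  expect_true(all(empty$counts == 0))
  expect_equal(empty$pct_genome_ge_200k, 0)
})

test_that("overlapping LDRs are symmetric intersections", {
  a <- data.frame(taxon = "I", chrom = "chr1", start = 0, end = 100000,
                  size = 100000, size_class = "<100")
  b <- data.frame(taxon = "J", chrom = "chr1", start = 50000, end = 150000,
                  size = 100000, size_class = "100-200")
  ov <- overlap_ldrs(a, b)
  expect_equal(ov[, c("start", "end")],
               data.frame(start = 50000, end = 100000))
  expect_equal(overlap_ldrs(b, a)[, c("start", "end")],
               ov[, c("start", "end")])
  # nested -> inner interval
  nested <- data.frame(taxon = "J", chrom = "chr1", start = 20000,
                       end = 30000, size = 10000, size_class = "<100")
  expect_equal(overlap_ldrs(a, nested)$start, 20000)
  expect_equal(overlap_ldrs(a, nested)$end, 30000)
  # disjoint -> empty
  far <- data.frame(taxon = "J", chrom = "chr2", start = 0, end = 10000,
                    size = 10000, size_class = "<100")
  expect_identical(nrow(overlap_ldrs(a, far)), 0L)
  # output covered by both inputs (random property)
  set.seed(11)
  for (i in 1:10) {
    mk <- function() {
      s <- sort(sample.int(100, 6)) * 1000
      data.frame(taxon = "x", chrom = "chr1", start = s[c(1, 3, 5)],
                 end = s[c(2, 4, 6)], size = s[c(2, 4, 6)] - s[c(1, 3, 5)],
                 size_class = NA)
    }
    x <- mk(); y <- mk()
    ov <- overlap_ldrs(x, y)
    if (nrow(ov)) {
      inside <- function(z) all(vapply(seq_len(nrow(ov)), function(i)
        any(z$start <= ov$start[i] & ov$end[i] <= z$end), TRUE))
      expect_true(inside(x) && inside(y))
    }
  }
})

test_that("the bottom fraction keeps the lowest tiles with stable ties", {
  rc <- data.frame(chrom = "chr1", start = (0:99) * 10000,
                   end = (1:100) * 10000,
                   median_theta = c(rep(1, 4), rep(2, 6), rep(5, 90)),
                   n_windows = 10L)
  expect_identical(nrow(bottom_fraction_ldrs(rc, 1)), 100L)
  low5 <- bottom_fraction_ldrs(rc, 0.05)
  expect_identical(nrow(low5), 5L)
  # ties at the boundary: the 5th slot goes to the earliest coordinate
  # among the theta = 2 tiles
  expect_identical(low5$start, c((0:4) * 10000))
  expect_error(bottom_fraction_ldrs(rc, 0), "fraction")
})
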
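test_that("genetic distance matches its closed forms", {
  expect_equal(genetic_distance(1, 0), 1)     # fixed difference
  expect_equal(genetic_distance(1, 1), 0)     # same fixed allele
  expect_equal(genetic_distance(0.5, 0.5), 0.5)
  expect_error(genetic_distance(numeric(), numeric()), "empty")
  # symmetry and range on random sites
  set.seed(61)
  p1 <- stats::runif(50); p2 <- stats::runif(50)
  expect_equal(genetic_distance(p1, p2), genetic_distance(p2, p1))
  expect_gte(genetic_distance(p1, p2), 0)
  expect_lte(genetic_distance(p1, p2), 1)
})

test_that("Weir Fst matches its oracles and boundary behaviour", {
  # fixed difference with equal sample sizes: within-population mean square
  # is zero -> Fst = 1
  expect_equal(weir_fst(1, 20, 0, 20), 1)
  # identical intermediate frequencies: raw estimate <= 0, clamped
  expect_equal(weir_fst(0.5, 22, 0.5, 22), 0)
  expect_lte((function(p, n) {            # raw (unclamped) value is negative
    msp <- 2 * n * (p - p)^2
    msg <- 2 * n * p * (1 - p) / (2 * n - 2)
    (msp - msg)
  })(0.5, 22), 0)
  expect_equal(weir_fst(0.9, 20, 0.1, 20), weir_oracle(0.9, 20, 0.1, 20),
               tolerance = 1e-14)
  # symmetric in the two populations
  expect_equal(weir_fst(0.8, 15, 0.3, 40), weir_fst(0.3, 40, 0.8, 15))
  expect_error(weir_fst(0, 10, 0, 12), "monomorphic")
  expect_error(weir_fst(0.5, 1, 0.5, 10))
})

test_that("Weir Fst agrees with the aov mean-square oracle on count data", {
  set.seed(62)
  for (i in 1:50) {
    n_a <- sample(5:60, 1); n_b <- sample(5:60, 1)
    k_a <- sample.int(n_a - 1, 1); k_b <- sample.int(n_b - 1, 1)
    expect_equal(weir_fst(k_a / n_a, n_a, k_b / n_b, n_b),
                 weir_aov_oracle(k_a, n_a, k_b, n_b), tolerance = 1e-12)
  }
})

test_that("site frequency filters drop low-coverage and singleton sites", {
  mk_pool <- function(m1, m2, taxon) {
    structure(list(taxon = taxon, L = nrow(m1), counts = list(m1, m2),
                   mean_coverage = NA, error_rates = c(NA, NA)),
              class = "pool_counts")
  }
  # 3 sites x 4 alleles; platform 2 contributes zero reads for simplicity
  z <- matrix(0L, 3, 4)
  R1 <- rbind(c(5, 4, 0, 0),    # depth 9 in R -> dropped
              c(20, 10, 0, 0),  # kept: p_R = 2/3
              c(29, 1, 0, 0))   # pooled variant count 1 -> dropped
  I1 <- rbind(c(20, 10, 0, 0), c(15, 5, 0, 0), c(30, 0, 0, 0))
  J1 <- rbind(c(25, 5, 0, 0), c(12, 12, 0, 0), c(30, 0, 0, 0))
  fr <- site_frequencies(list(R = mk_pool(R1, z, "R"),
                              I = mk_pool(I1, z, "I"),
                              J = mk_pool(J1, z, "J")), min_depth = 10)
  expect_identical(fr$pos, 1L)              # only the middle site survives
  expect_equal(fr$p_I, 0.75)                # 15 ref / 5 alt
  expect_equal(fr$p_R, 2 / 3)
  expect_equal(fr$p_J, 0.5)
  expect_error(site_frequencies(list(R = mk_pool(R1, z, "R"))), "taxon")
})

test_that("monomorphic-pair sites get Fst 0 in site records", {
  fr <- data.frame(p_R = c(0.5, 0.2), p_I = c(1, 0.9), p_J = c(1, 0.8))
  rec <- fst_site_records(fr, n_R = 46, n_I = 22, n_J = 21)
  expect_equal(rec$fst_IJ[1], 0)            # I and J both fixed, same allele
  expect_gt(rec$fst_RI[1], 0)
  expect_equal(rec$fst_IJ[2], weir_fst(0.9, 22, 0.8, 21))
})

test_that("conditioning keeps the threshold site and preserves identity at 0", {
  rec <- data.frame(fst_RI = c(0.5, 0.49, 0.8), x = 1:3)
  expect_identical(conditional_sites(rec, 0.5)$x, c(1L, 3L))  # >= keeps 0.5
  expect_identical(conditional_sites(rec, 0), rec)
  expect_identical(nrow(conditional_sites(rec, 0.9)), 0L)
})

test_that("the ECDF D statistic matches brute force", {
  expect_equal(ecdf_d_statistic(1:5, 1:5), 0)
  expect_equal(ecdf_d_statistic(1:5, 6:10), 1)
  expect_equal(ecdf_d_statistic(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4)), 1 / 3)
  expect_error(ecdf_d_statistic(numeric(), 1:3), "empty")
  set.seed(63)
  for (i in 1:50) {
    a <- round(stats::runif(sample(2:12, 1)), 2)
    b <- round(stats::runif(sample(2:12, 1)), 2)
    expect_equal(ecdf_d_statistic(a, b), brute_force_D(a, b),
                 tolerance = 1e-14)
  }
})

test_that("the region KS screen requires both left shifts", {
  # identical distributions: never significant
  same <- data.frame(fst_IJ = seq(0, 1, length = 30),
                     fst_RI = seq(0, 1, length = 30),
                     fst_RJ = seq(0, 1, length = 30))
  expect_false(region_ks_test(same)$significant)
  # complete separation: significant
  sep <- data.frame(fst_IJ = rep(0, 25), fst_RI = rep(1, 25),
                    fst_RJ = rep(1, 25))
  expect_true(region_ks_test(sep)$significant)
  # left shift against only one reference: not significant
  half <- data.frame(fst_IJ = rep(0, 25), fst_RI = rep(0, 25),
                     fst_RJ = rep(1, 25))
  expect_false(region_ks_test(half)$significant)
  # too few sites: untestable, not significant
  tiny <- region_ks_test(sep[1:3, ])
  expect_false(tiny$testable)
  expect_false(tiny$significant)
})
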
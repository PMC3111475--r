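test_that("pair coalescence time matches the analytic expectation", {
  # haploid pair in a constant-size population: E[T2] = 2N generations
  # = 0.5 in units of 4N generations
  m <- test_model()
  set.seed(71)
  t2 <- replicate(2500, {
    g <- two_phase_genealogy(m, 100, c(n_R = 2, n_I = 0, n_J = 0))
    max(g[[1]]$time)
  })
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 0.5), 3 * se)
})

test_that("expected segregating sites follow E[S] = a_n * theta", {
  m <- test_model()
  n <- 10; theta <- 0.01; L <- 1000
  set.seed(72)
  S <- replicate(1500, ncol(simulate_locus(m, L,
                                           c(n_R = n, n_I = 0, n_J = 0),
                                           theta = theta)$mat))
  expected <- harmonic_oracle(n - 1) * theta * L
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3.5 * se)
})

test_that("zero mutation rate yields zero segregating sites", {
  g <- two_phase_genealogy(test_model(), 1000, c(n_R = 5, n_I = 5, n_J = 5),
                           seed = 3)
  smp <- overlay_mutations(g, theta = 0)
  expect_identical(ncol(smp$mat), 0L)
  expect_error(overlay_mutations(g, theta = -1), "theta")
})

test_that("mutation counts are Poisson given the genealogy", {
  g <- two_phase_genealogy(test_model(), 2000, c(n_R = 6, n_I = 5, n_J = 5),
                           seed = 4)
  lt <- genealogy_total_length(g)
  theta <- 0.02
  set.seed(73)
  S <- replicate(600, ncol(overlay_mutations(g, theta = theta)$mat))
  expect_lt(abs(mean(S) - theta * lt), 3.5 * sd(S) / sqrt(length(S)))
  # index of dispersion of a Poisson is 1
  expect_gt(var(S) / mean(S), 0.8)
  expect_lt(var(S) / mean(S), 1.25)
})

test_that("full selfing shares one cultivar genealogy across sub-segments", {
  m <- test_model(recomb_rate = 1e-8)   # several sub-segments per locus
  g <- two_phase_genealogy(m, 5000, c(n_R = 4, n_I = 8, n_J = 8), seed = 5)
  expect_gt(length(g), 1)
  dom <- m$T_d
  # ancestral chain of every cultivar leaf up to the domestication time:
  # identical across sub-segments iff the selfing-phase forest is shared
  forest_chains <- function(seg) {
    lapply(5:20, function(leaf) {
      v <- leaf; chain <- numeric()
      repeat {
        p <- seg$parent[v] + 1L          # parents are 0-based, -1 = root
        if (seg$parent[v] < 0 || seg$time[p] > dom) break
        chain <- c(chain, seg$time[p]); v <- p
      }
      chain
    })
  }
  ref <- forest_chains(g[[1]])
  for (seg in g[-1]) expect_equal(forest_chains(seg), ref)
})

test_that("sequential domestication draws the cultivars together", {
  set.seed(74)
  # per-replicate (IJ, RI) mean pairwise differences: compare the means
  seq_d <- replicate(250, {
    s <- simulate_locus(scan_model("sequential"), 1500,
                        c(n_R = 8, n_I = 8, n_J = 8))
    if (ncol(s$mat) == 0) return(c(NA, NA))
    fI <- colMeans(s$mat[s$taxa == "I", , drop = FALSE])
    fJ <- colMeans(s$mat[s$taxa == "J", , drop = FALSE])
    fR <- colMeans(s$mat[s$taxa == "R", , drop = FALSE])
    c(sum(fI * (1 - fJ) + fJ * (1 - fI)),
      sum(fR * (1 - fI) + fI * (1 - fR)))
  })
  expect_lt(mean(seq_d[1, ], na.rm = TRUE), mean(seq_d[2, ], na.rm = TRUE))
})

test_that("independent symmetric histories give a trifurcation", {
  m <- demographic_model("independent", N_I = 1.5e4, N_J = 1.5e4)
  set.seed(75)
  d <- replicate(400, {
    s <- simulate_locus(m, 1000, c(n_R = 8, n_I = 8, n_J = 8))
    if (ncol(s$mat) == 0) return(c(NA, NA))
    fI <- colMeans(s$mat[s$taxa == "I", , drop = FALSE])
    fJ <- colMeans(s$mat[s$taxa == "J", , drop = FALSE])
    fR <- colMeans(s$mat[s$taxa == "R", , drop = FALSE])
    c(sum(fR * (1 - fI) + fI * (1 - fR)),
      sum(fR * (1 - fJ) + fJ * (1 - fR)))
  })
  rel <- abs(mean(d[1, ], na.rm = TRUE) - mean(d[2, ], na.rm = TRUE)) /
    mean(d, na.rm = TRUE)
  expect_lt(rel, 0.1)
})

test_that("seeded simulations are bit-reproducible", {
  m <- test_model()
  s1 <- simulate_locus(m, 3000, seed = 99)
  s2 <- simulate_locus(m, 3000, seed = 99)
  expect_identical(s1, s2)
  g1 <- simulate_three_taxon_genome(m, 3, 1000, seed = 99)
  g2 <- simulate_three_taxon_genome(m, 3, 1000, seed = 99)
  expect_identical(g1, g2)
})

test_that("invalid genealogy inputs are rejected", {
  m <- test_model()
  expect_error(two_phase_genealogy(m, -5), "positive")
  expect_error(two_phase_genealogy(m, 100, c(n_R = 1, n_I = 0, n_J = 0)))
})

test_that("ms-style text output carries the haplotype matrix", {
  smp <- simulate_locus(test_model(), 2000, seed = 8)
  path <- withr::local_tempfile(fileext = ".ms")
  write_ms(smp, path)
  lines <- readLines(path)
  expect_identical(lines[1], "//")
  expect_identical(lines[2], sprintf("segsites: %d", ncol(smp$mat)))
  expect_identical(length(lines), 3L + nrow(smp$mat))
  expect_identical(nchar(lines[4]), ncol(smp$mat))
})
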
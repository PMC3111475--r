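# Independent reference implementations used as oracles in the tests.
# These deliberately use different algorithms / code paths from the package.

# two-sample KS D by brute force: evaluate both ECDFs at every pooled point
brute_force_D <- function(a, b) {
  pts <- c(a, b)
  d <- 0
  for (x in pts) {
    fa <- sum(a <= x) / length(a)
    fb <- sum(b <= x) / length(b)
    d <- max(d, abs(fa - fb))
  }
  d
}

# Weir-Cockerham haploid Fst via long-form variance-component sums
# (independent of the vectorised package formulas)
weir_oracle <- function(p_a, n_a, p_b, n_b) {
  r <- 2
  n <- c(n_a, n_b)
  p <- c(p_a, p_b)
  nbar <- sum(n) / r
  pbar <- sum(n * p) / sum(n)
  msp <- 0
  for (i in 1:r) msp <- msp + n[i] * (p[i] - pbar)^2
  msp <- msp / (r - 1)
  msg <- 0
  for (i in 1:r) msg <- msg + n[i] * p[i] * (1 - p[i])
  msg <- msg / sum(n - 1)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  f <- (msp - msg) / (msp + (nc - 1) * msg)
  min(max(f, 0), 1)
}

# Weir-Cockerham haploid Fst via stats::aov mean squares on 0/1 indicator
# data (exact when frequencies are integer allele counts / n)
weir_aov_oracle <- function(k_a, n_a, k_b, n_b) {
  y <- c(rep(1, k_a), rep(0, n_a - k_a), rep(1, k_b), rep(0, n_b - k_b))
  pop <- factor(rep(c("a", "b"), times = c(n_a, n_b)))
  ms <- summary(stats::aov(y ~ pop))[[1]][["Mean Sq"]]
  nc <- (n_a + n_b - (n_a^2 + n_b^2) / (n_a + n_b))
  f <- (ms[1] - ms[2]) / (ms[1] + (nc - 1) * ms[2])
  min(max(f, 0), 1)
}

# harmonic number sum, written out (oracle for the Watterson normaliser)
harmonic_oracle <- function(m) {
  s <- 0
  for (i in 1:m) s <- s + 1 / i
  s
}

# total branch length (weighted by sub-segment length) of a locus genealogy,
# in units of 4*N_R generations * bp
genealogy_total_length <- function(g) {
  tot <- 0
  for (seg in g) {
    len <- seg$end - seg$start
    for (v in seq_along(seg$parent)) {
      p <- seg$parent[v]
      if (p >= 0) tot <- tot + len * (seg$time[p + 1] - seg$time[v])
    }
  }
  tot
}

# small default models shared across tests
test_model <- function(...) demographic_model("independent", ...)

# scaled-down demography used for the genealogy-contrast experiments
scan_model <- function(topology = "independent", ...)
  demographic_model(topology, N_I = 2e4, N_J = 1e4, ...)
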
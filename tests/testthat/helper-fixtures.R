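# units table for a homogeneous genome: per-1kb-unit segregating counts from
# independent coalescent loci (n lineages, theta per kb), all sites callable
homogeneous_units <- function(n_units, n = 22, theta_kb = 4,
                              chroms = c(chr1 = 0.5, chr2 = 0.5)) {
  m <- test_model(mut_rate_theta = theta_kb / 1000)
  S <- vapply(seq_len(n_units), function(i)
    ncol(simulate_locus(m, 1000, c(n_R = n, n_I = 0, n_J = 0))$mat),
    integer(1))
  sizes <- round(n_units * chroms)
  sizes[length(sizes)] <- n_units - sum(sizes[-length(sizes)])
  data.frame(chrom = rep(names(chroms), sizes),
             start = unlist(lapply(sizes, function(k) (seq_len(k) - 1) * 1000)),
             S = S, callable = 1000L)
}

# independent re-implementation of one shuffle used as an oracle: permute
# units, tile non-overlapping windows per chromosome, return all window
# thetas (callable rule included)
shuffle_once_oracle <- function(units, n, per_win = 100) {
  perm <- sample.int(nrow(units))
  S <- units$S[perm]; C <- units$callable[perm]
  sizes <- table(factor(units$chrom, unique(units$chrom)))
  thetas <- c()
  off <- 0
  for (m in sizes) {
    nw <- m %/% per_win
    for (w in seq_len(nw)) {
      i <- off + (w - 1) * per_win + seq_len(per_win)
      if (sum(C[i]) >= 10000)
        thetas <- c(thetas, 1000 * sum(S[i]) / (harmonic_oracle(n - 1) * sum(C[i])))
    }
    off <- off + m
  }
  thetas
}
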
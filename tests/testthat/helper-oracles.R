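# Brute-force leave-one-out reference: explicit loops, means via sum/length,
# independent of the package implementation.
oracle_classify <- function(trials_a, trials_b, scheme) {
  bins <- function(t) {
    v <- numeric(scheme$n_bins)
    for (x in t) {
      if (x >= scheme$window[1] && x < scheme$window[2]) {
        b <- floor((x - scheme$window[1]) / scheme$bin_ms) + 1
        v[b] <- v[b] + 1
      }
    }
    v
  }
  A <- lapply(trials_a, bins); B <- lapply(trials_b, bins)
  score <- function(own, other) {
    res <- character(0)
    for (i in seq_along(own)) {
      t_own <- Reduce(`+`, own[-i]) / (length(own) - 1)
      t_other <- Reduce(`+`, other) / length(other)
      d1 <- sum((own[[i]] - t_own)^2)
      d2 <- sum((own[[i]] - t_other)^2)
      res <- c(res, if (d1 < d2) "correct" else if (d1 > d2) "wrong" else "tie")
    }
    res
  }
  c(score(A, B), score(B, A))
}

# Exact two-sided rank-sum p by enumerating every assignment of the pooled
# observations to the two groups.
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
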
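# Independent small-sample oracles for the rank tests.

# All permutations of a small vector, base R only.
combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Exhaustive permutation p-value for the Friedman statistic: enumerate every
# assignment of within-block rank orders (k!^N for untied data) and count how
# often the rank-sum statistic reaches the observed one.
perm_friedman_p <- function(mat) {
  k <- ncol(mat)
  N <- nrow(mat)
  stat_from_ranks <- function(r) {
    Rj <- colSums(r)
    12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
  }
  obs <- stat_from_ranks(t(apply(mat, 1, rank)))
  all_orders <- matrix(unlist(combinat_perms(seq_len(k))), ncol = k, byrow = TRUE)
  perms <- as.matrix(expand.grid(rep(list(seq_len(nrow(all_orders))), N)))
  stats <- apply(perms, 1, function(idx) {
    stat_from_ranks(all_orders[idx, , drop = FALSE])
  })
  mean(stats >= obs - 1e-9)
}
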
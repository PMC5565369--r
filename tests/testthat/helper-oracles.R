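# Independent brute-force Mann-Whitney oracle: enumerate every assignment
# of the pooled values to group A and compute the exact two-sided p as the
# doubled smaller tail of the permutation distribution of U.
brute_force_mw <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  U_of <- function(sel) {
    av <- pooled[sel]; bv <- pooled[-sel]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  U_all <- apply(idx, 2, U_of)
  U_obs <- U_of(seq_len(n_a))
  m <- n_a * (length(pooled) - n_a)
  p <- if (U_obs > m / 2) 2 * mean(U_all >= U_obs) else 2 * mean(U_all <= U_obs)
  list(U = U_obs, p = min(1, p))
}
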
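# Independent oracles used by the tests. These deliberately avoid the
# package's own machinery: plain-R Monte Carlo for overlap probabilities and
# a direct-method Gillespie simulator for the well-mixed cascade.

# P(|X - Y| < sigma) for X, Y uniform in the shell [rin, rout], by plain
# Monte Carlo with R's own RNG.
mc_pair_overlap_prob <- function(rin, rout, sigma, n = 4e5) {
  draw <- function(n) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- (rin^3 + (rout^3 - rin^3) * runif(n))^(1 / 3)
    u * r
  }
  x <- draw(n)
  y <- draw(n)
  mean(sqrt(rowSums((x - y)^2)) < sigma)
}

# P(uniform X in shell within sigma of a fixed point at radius a)
mc_point_overlap_prob <- function(rin, rout, a, sigma, n = 4e5) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- (rin^3 + (rout^3 - rin^3) * runif(n))^(1 / 3)
  x <- u * r
  mean(sqrt((x[, 1] - a)^2 + x[, 2]^2 + x[, 3]^2) < sigma)
}

# Direct-method Gillespie simulation of the well-mixed mass-action analogue
# of the cascade: catalytic activation (receptor -> Ras -> Raf -> ERK) plus
# first-order inactivation. Rates per pair per minute. Uses R's RNG.
# counts: c(ras, raf, erk); k_act: c(rec_ras, ras_raf, raf_erk) per-pair
# rates; k_off: per-species inactivation rates; n_rec: active receptors.
ssa_cascade <- function(counts, n_rec, k_act, k_off, t_end, times) {
  on <- c(0, 0, 0)
  t <- 0
  out <- matrix(0, nrow = length(times), ncol = 3)
  ti <- 1
  repeat {
    off <- counts - on
    a <- c(off[1] * n_rec * k_act[1],
           off[2] * on[1] * k_act[2],
           off[3] * on[2] * k_act[3],
           on * k_off)
    a0 <- sum(a)
    tnext <- if (a0 > 0) t + rexp(1, a0) else Inf
    while (ti <= length(times) && times[ti] < min(tnext, t_end)) {
      out[ti, ] <- on
      ti <- ti + 1
    }
    if (tnext >= t_end || ti > length(times)) break
    t <- tnext
    j <- sample.int(6, 1, prob = a / a0)
    if (j <= 3) on[j] <- on[j] + 1 else on[j - 3] <- on[j - 3] - 1
  }
  out
}

# ensemble mean of the SSA oracle at the given times
ssa_ensemble <- function(reps, counts, n_rec, k_act, k_off, t_end, times) {
  acc <- matrix(0, nrow = length(times), ncol = 3)
  for (r in seq_len(reps))
    acc <- acc + ssa_cascade(counts, n_rec, k_act, k_off, t_end, times)
  acc / reps
}
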
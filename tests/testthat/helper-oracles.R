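# Independent oracles used across tests. These deliberately avoid the
# package's log-sum-exp code paths.

# Wakefield log ABF as an explicit density ratio of the two marginal
# likelihoods of beta_hat
oracle_labf <- function(z, V, W) {
  bhat <- z * sqrt(V)
  dnorm(bhat, 0, sqrt(V + W), log = TRUE) - dnorm(bhat, 0, sqrt(V), log = TRUE)
}

# brute-force enumeration of the Q+1 single-causal configurations on the
# linear scale (valid for the moderate lbf magnitudes used in tests)
oracle_posteriors <- function(lbf, pn, pa, pc, q) {
  bf <- exp(lbf)
  mass <- c(pn, pa * bf[-q], pc * bf[q])          # null, Q-1 others, query
  mass <- mass / sum(mass)
  c(ppHn = mass[1L], ppHa = sum(mass[2:(length(bf))]),
    ppHc = mass[length(mass)])
}

# naive filter-and-average FDR
oracle_fdr <- function(pphc, t) {
  kept <- c()
  for (p in pphc) if (p > t) kept <- c(kept, p)
  if (!length(kept)) return(NA_real_)
  1 - sum(kept) / length(kept)
}

# exhaustive BH step-up scan
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * alpha / m) kmax <- k
  if (kmax == 0) rep(FALSE, m) else p <= ps[kmax]
}

# small toy region used in several io/bf tests
toy_region <- function(Q = 5L, query = 2L, z = NULL, seed = 1) {
  set.seed(seed)
  z <- z %||% rnorm(Q)
  maf <- runif(Q, 0.05, 0.5)
  se <- 1 / sqrt(2 * maf * (1 - maf) * 20000 * 0.25)
  region_summary(snp_ids = sprintf("1_%d_A_G", 1000L + seq_len(Q)),
                 beta = z * se, se = se, maf = maf, n = 20000, s = 0.5,
                 trait_type = "cc", query_index = query, trait_id = "toy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shorthand around the internal constructor
bf_dec <- function(lbf, method = "ABF") phescan:::bf_decomposition(lbf, method)
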
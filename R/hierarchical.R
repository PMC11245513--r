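#' Parameters of the hierarchical prior model
#'
#' The region priors are generated by a softmax over the `Q + 1`
#' single-causal configurations with the null configuration as reference:
#' with `Dx = 1 + (Q-1) exp(alpha) + exp(alpha + beta + gamma x)`,
#' `pn = 1/Dx`, `pa = exp(alpha)/Dx` and
#' `pc = exp(alpha + beta + gamma x)/Dx`, where `x` is an optional
#' per-region covariate (e.g. genetic correlation with the primary trait).
#' `alpha` sets the per-SNP log-odds of a non-query causal variant, `beta`
#' the log enrichment of the query variant (`pc/pa = exp(beta + gamma x)`),
#' and `gamma` the covariate effect on the Hc propensity.
#'
#' @param alpha,beta,gamma finite reals; `gamma` defaults to 0.
#' @export
hier_params <- function(alpha, beta, gamma = 0) {
  v <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(v))) stop_validation("hier_params must be finite")
  structure(as.list(v), class = "hier_params")
}

#' Region prior set implied by hierarchical parameters
#'
#' Computed in log space so the constraint `pn + (Q-1) pa + pc = 1` holds
#' to machine precision and extreme parameter values cannot overflow.
#'
#' @param params a [hier_params()].
#' @param x covariate value for this region; default 0.
#' @param Q number of SNPs in the region.
#' @return a [prior_set()].
#' @export
priors_from_params <- function(params, x = 0, Q) {
  if (Q < 2L) stop_validation("Q must be >= 2")
  la <- params$alpha
  lc <- params$alpha + params$beta + params$gamma * x
  lD <- logsumexp(c(0, log(Q - 1) + la, lc))
  prior_set(pa = exp(la - lD), pc = exp(lc - lD), Q = Q)
}

#' Sufficient statistics of a Bayes factor decomposition for the
#' hierarchical likelihood
#'
#' Each (region, signal) contributes a likelihood term
#' `pn + pa * sum_{j != q} BF_j + pc * BF_q`, so only
#' `S = log sum_{j != q} exp(lbf_j)` and `lq = lbf_q` are needed per
#' signal, plus the region's `Q` and covariate.
#'
#' @param bf a [bf_decomposition()].
#' @param query_index 1-based query variant index.
#' @param trait_id trait label.
#' @param x covariate value; default 0.
#' @return data.frame with one row per signal: `trait_id`, `signal`, `S`,
#'   `lq`, `Q`, `x`.
#' @export
region_stats <- function(bf, query_index, trait_id = NA_character_, x = 0) {
  Q <- ncol(bf$lbf)
  if (is.na(query_index) || query_index < 1L || query_index > Q)
    stop_validation("query_index out of range")
  L <- nrow(bf$lbf)
  data.frame(
    trait_id = trait_id, signal = seq_len(L),
    S = vapply(seq_len(L), function(l) logsumexp(bf$lbf[l, -query_index]), 0),
    lq = bf$lbf[, query_index], Q = Q, x = x)
}

# vectorized log(exp(a0) + exp(a1) + exp(a2)) over aligned vectors
lse3 <- function(a0, a1, a2) {
  m <- pmax(a0, a1, a2)
  m + log(exp(a0 - m) + exp(a1 - m) + exp(a2 - m))
}

#' Marginal log-likelihood of the dataset given hierarchical parameters
#'
#' Sums over all (region, signal) rows the log of the hypothesis-
#' marginalized likelihood
#' `pn * 1 + pa * sum_{j != q} BF_j + pc * BF_q`, with the region-specific
#' prior set generated by [priors_from_params()]. When all Bayes factors
#' are 1 each term is exactly `pn + (Q-1) pa + pc = 1` and the
#' log-likelihood is 0.
#'
#' @param params a [hier_params()].
#' @param stats data.frame of [region_stats()] rows (columns `S`, `lq`,
#'   `Q`, `x`).
#' @return scalar log-likelihood.
#' @export
dataset_loglik <- function(params, stats) {
  a <- params$alpha
  lc <- a + params$beta + params$gamma * stats$x
  lD <- lse3(rep(0, nrow(stats)), log(stats$Q - 1) + a, lc)
  sum(lse3(rep(0, nrow(stats)), a + stats$S, lc + stats$lq) - lD)
}

#' MCMC settings for the hierarchical model
#'
#' @param n_iter total Metropolis iterations; default 30000 (use 3e5-1e6
#'   for production-scale datasets).
#' @param thin retain every `thin`-th iteration; default 30.
#' @param burn_fraction fraction of the retained, thinned chain discarded
#'   as burn-in before averaging; default 0.5.
#' @param proposal_sd Gaussian random-walk proposal standard deviations
#'   for (alpha, beta, gamma).
#' @param seed RNG seed.
#' @param prior_mean,prior_sd Gaussian hyper-prior means and sds for
#'   (alpha, beta, gamma); defaults N(-10,5), N(0,5), N(0,2), weakly
#'   informative on plausible per-SNP scales.
#' @param adapt adapt a global proposal scale towards 30% acceptance
#'   during the burn-in window only (frozen afterwards, preserving
#'   detailed balance for the averaged samples); default TRUE.
#' @export
mcmc_config <- function(n_iter = 30000L, thin = 30L, burn_fraction = 0.5,
                        proposal_sd = c(0.1, 0.1, 0.1), seed = 1L,
                        prior_mean = c(-10, 0, 0), prior_sd = c(5, 5, 2),
                        adapt = TRUE) {
  if (n_iter < thin || thin < 1L) stop_validation("need n_iter >= thin >= 1")
  if (burn_fraction < 0 || burn_fraction >= 1)
    stop_validation("burn_fraction in [0, 1)")
  structure(list(n_iter = as.integer(n_iter), thin = as.integer(thin),
                 burn_fraction = burn_fraction,
                 proposal_sd = rep_len(proposal_sd, 3L),
                 seed = as.integer(seed),
                 prior_mean = rep_len(prior_mean, 3L),
                 prior_sd = rep_len(prior_sd, 3L), adapt = adapt),
            class = "mcmc_config")
}

#' Fit the hierarchical prior model by random-walk Metropolis
#'
#' Learns (alpha, beta, gamma) from all (region, signal) Bayes factor
#' statistics jointly, then averages the implied region priors and
#' hypothesis posteriors over the post-burn-in thinned chain.
#'
#' @param stats data.frame of [region_stats()] rows for the whole dataset.
#' @param config an [mcmc_config()].
#' @param use_covariate include the `gamma * x` covariate term? Default:
#'   yes when `stats$x` has any nonzero value. When FALSE, gamma is held
#'   at 0 but the RNG stream is identical to the covariate model's, so
#'   the two fits agree exactly when gamma is pinned.
#' @return object of class `chain_summary`: `samples` (data.frame:
#'   iteration, alpha, beta, gamma, loglik, accepted), `acceptance`,
#'   `params_mean`, `post_samples` (post-burn-in matrix), `priors`
#'   (per-region averaged pn/pa/pc), `posteriors` (per-signal averaged
#'   ppHn/ppHa/ppHc), `warning` (acceptance-rate diagnostic or NULL).
#' @export
mcmc_run <- function(stats, config = mcmc_config(), use_covariate = NULL) {
  if (nrow(stats) == 0L) stop_validation("empty dataset")
  use_covariate <- use_covariate %||% any(stats$x != 0)
  x <- if (use_covariate) stats$x else rep(0, nrow(stats))
  st <- data.frame(S = stats$S, lq = stats$lq, Q = stats$Q, x = x)
  mask <- c(1, 1, as.numeric(use_covariate))
  set.seed(config$seed)
  p <- config$prior_mean * mask
  log_prior <- function(p) sum(stats::dnorm(p, config$prior_mean,
                                            config$prior_sd, log = TRUE))
  ll <- dataset_loglik(hier_params(p[1L], p[2L], p[3L]), st)
  lpost <- ll + log_prior(p)
  n_keep <- config$n_iter %/% config$thin
  samples <- matrix(NA_real_, n_keep, 6L,
                    dimnames = list(NULL, c("iteration", "alpha", "beta",
                                            "gamma", "loglik", "accepted")))
  scale <- 1
  burn_raw <- floor(config$burn_fraction * config$n_iter)
  acc_window <- 0L
  n_acc <- 0L
  k <- 0L
  for (it in seq_len(config$n_iter)) {
    eps <- stats::rnorm(3L) * config$proposal_sd * scale * mask
    u <- stats::runif(1L)
    prop <- p + eps
    ll_prop <- dataset_loglik(hier_params(prop[1L], prop[2L], prop[3L]), st)
    lpost_prop <- ll_prop + log_prior(prop)
    acc <- log(u) < lpost_prop - lpost
    if (acc) { p <- prop; ll <- ll_prop; lpost <- lpost_prop; n_acc <- n_acc + 1L
               acc_window <- acc_window + 1L }
    if (config$adapt && it <= burn_raw && it %% 100L == 0L) {
      scale <- scale * exp((acc_window / 100 - 0.3) * 0.5)
      acc_window <- 0L
    }
    if (it %% config$thin == 0L) {
      k <- k + 1L
      samples[k, ] <- c(it, p[1L], p[2L], p[3L], ll, acc)
    }
  }
  acceptance <- n_acc / config$n_iter
  post <- samples[-seq_len(floor(config$burn_fraction * n_keep)), ,
                  drop = FALSE]
  avg <- average_over_chain(post[, c("alpha", "beta", "gamma"),
                                 drop = FALSE], stats, x)
  warning_msg <- NULL
  if (acceptance < 0.05 || acceptance > 0.8)
    warning_msg <- sprintf(
      "acceptance rate %.3f outside [0.05, 0.8]: check mixing", acceptance)
  structure(list(samples = as.data.frame(samples), acceptance = acceptance,
                 params_mean = colMeans(post[, c("alpha", "beta", "gamma"),
                                             drop = FALSE]),
                 post_samples = post, priors = avg$priors,
                 posteriors = avg$posteriors, use_covariate = use_covariate,
                 warning = warning_msg),
            class = "chain_summary")
}

# average region priors and per-signal posteriors over retained samples
average_over_chain <- function(draws, stats, x) {
  n <- nrow(stats)
  acc_pr <- matrix(0, n, 3L)
  acc_po <- matrix(0, n, 3L)
  zero <- rep(0, n)
  lQm1 <- log(stats$Q - 1)
  for (s in seq_len(nrow(draws))) {
    a <- draws[s, 1L]; b <- draws[s, 2L]; g <- draws[s, 3L]
    lc <- a + b + g * x
    lD <- lse3(zero, lQm1 + a, lc)
    acc_pr <- acc_pr + cbind(exp(-lD), exp(a - lD), exp(lc - lD))
    t1 <- a + stats$S
    t2 <- lc + stats$lq
    lm <- lse3(zero, t1, t2)
    acc_po <- acc_po + cbind(exp(-lm), exp(t1 - lm), exp(t2 - lm))
  }
  acc_pr <- acc_pr / nrow(draws)
  acc_po <- acc_po / nrow(draws)
  list(priors = data.frame(trait_id = stats$trait_id, signal = stats$signal,
                           pn = acc_pr[, 1L], pa = acc_pr[, 2L],
                           pc = acc_pr[, 3L]),
       posteriors = data.frame(trait_id = stats$trait_id,
                               signal = stats$signal,
                               ppHn = acc_po[, 1L], ppHa = acc_po[, 2L],
                               ppHc = acc_po[, 3L]))
}

#' @export
print.chain_summary <- function(x, ...) {
  cat(sprintf(paste0("<chain_summary> %d retained samples, acceptance %.2f\n",
                     "  posterior mean: alpha=%.2f beta=%.2f gamma=%.2f",
                     " (pc/pa ~ %.2f at x=0)\n"),
              nrow(x$samples), x$acceptance, x$params_mean[1L],
              x$params_mean[2L], x$params_mean[3L], exp(x$params_mean[2L])))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Dump a chain as a tab-delimited trace
#' @param chain a `chain_summary`.
#' @param path output path.
#' @export
write_chain <- function(chain, path) {
  data.table::fwrite(chain$samples, path, sep = "\t")
  invisible(path)
}
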
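#' Configuration for the sum-of-single-effects decomposition
#'
#' @param L_max maximum number of single effects; default 10.
#' @param max_iter maximum IBSS iterations; default 100.
#' @param tol convergence tolerance on the change in posterior effect
#'   means; default 1e-3.
#' @param coverage credible-set posterior mass; default 0.95.
#' @param min_purity minimum absolute pairwise LD among credible-set
#'   members (singleton sets have purity 1); default 0.5.
#' @param prior_variance grid of candidate per-effect prior variances on
#'   the z-score scale, including 0 (the null effect); the per-effect value
#'   is chosen by maximizing the single-effect marginal likelihood.
#' @export
susie_config <- function(L_max = 10L, max_iter = 100L, tol = 1e-3,
                         coverage = 0.95, min_purity = 0.5,
                         prior_variance = c(0, 1, 2, 4, 8, 16, 32, 64,
                                            128, 256, 512, 1024)) {
  if (L_max < 1L) stop_validation("L_max must be >= 1")
  if (coverage <= 0 || coverage >= 1) stop_validation("coverage in (0,1)")
  if (min_purity < 0 || min_purity > 1) stop_validation("min_purity in [0,1]")
  if (!any(prior_variance == 0)) prior_variance <- c(0, prior_variance)
  structure(list(L_max = as.integer(L_max), max_iter = as.integer(max_iter),
                 tol = tol, coverage = coverage, min_purity = min_purity,
                 prior_variance = sort(prior_variance)),
            class = "susie_config")
}

# single-effect regression on a residualized z vector: choose the prior
# variance W on a grid by maximizing the marginal likelihood under a
# uniform prior over SNPs, then form posterior inclusion weights and means
single_effect_fit <- function(zr, config) {
  Q <- length(zr)
  best <- list(W = 0, loglik = -Inf, labf = rep(0, Q))
  for (W in config$prior_variance) {
    labf <- wakefield_labf(zr, 1, W)
    ll <- logsumexp(labf) - log(Q)
    if (ll > best$loglik + 1e-12) best <- list(W = W, loglik = ll, labf = labf)
  }
  alpha <- exp(best$labf - logsumexp(best$labf))
  mu1 <- (best$W / (1 + best$W)) * zr
  list(W = best$W, labf = best$labf, alpha = alpha, b = alpha * mu1)
}

credible_set <- function(alpha, coverage) {
  ord <- order(alpha, decreasing = TRUE)
  k <- which(cumsum(alpha[ord]) >= coverage)[1L]
  if (is.na(k)) k <- length(alpha)
  sort(ord[seq_len(k)])
}

set_purity <- function(cs, ld) {
  if (length(cs) == 1L) return(1)
  sub <- abs(unclass(ld)[cs, cs])
  min(sub[upper.tri(sub)])
}

#' Sum-of-single-effects decomposition of regional z-scores
#'
#' Minimal SuSiE on the regression-with-summary-statistics (RSS)
#' likelihood `z ~ MVN(R lambda, R)`: iterative Bayesian stepwise selection
#' fits up to `L_max` single effects, each a Wakefield-style single-SNP
#' regression on the z-scores residualized for the other effects, with a
#' per-effect prior variance chosen on a grid (including the null). Effects
#' whose 95% credible set fails the coverage/purity filter, or whose
#' estimated prior variance is 0, are dropped. The retained per-effect rows
#' of per-SNP log Bayes factors feed [region_posteriors()] exactly like an
#' ABF row, one signal at a time.
#'
#' @param z numeric vector of z-scores, length `Q`.
#' @param ld an [ld_matrix()] of dimension `Q` (regularized).
#' @param config a [susie_config()].
#' @return a [bf_decomposition()] with `method = "SuSiE"`, zero or more
#'   signal rows, `credible_sets` (1-based index vectors) and `converged`.
#' @export
susie_rss <- function(z, ld, config = susie_config()) {
  Q <- length(z)
  if (nrow(ld) != Q)
    stop_validation("length(z) = ", Q, " but LD is ", nrow(ld), " x ", ncol(ld))
  R <- unclass(ld)
  L <- min(config$L_max, Q)
  B <- matrix(0, L, Q)          # per-effect posterior mean coefficients
  fits <- vector("list", L)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    B_old <- B
    fitted_all <- colSums(B)
    for (l in seq_len(L)) {
      zr <- z - drop(R %*% (fitted_all - B[l, ]))
      fit <- single_effect_fit(zr, config)
      fitted_all <- fitted_all - B[l, ] + fit$b
      B[l, ] <- fit$b
      fits[[l]] <- fit
    }
    if (max(abs(B - B_old)) < config$tol) { converged <- TRUE; break }
  }
  keep <- integer(0)
  sets <- list()
  for (l in seq_len(L)) {
    if (fits[[l]]$W == 0) next
    cs <- credible_set(fits[[l]]$alpha, config$coverage)
    if (set_purity(cs, ld) < config$min_purity) next
    if (any(vapply(sets, identical, TRUE, y = cs))) next  # duplicate signal
    keep <- c(keep, l)
    sets <- c(sets, list(cs))
  }
  lbf <- matrix(numeric(0), 0L, Q, dimnames = list(NULL, rownames(ld)))
  if (length(keep))
    lbf <- matrix(t(vapply(fits[keep], `[[`, numeric(Q), "labf")),
                  nrow = length(keep), ncol = Q,
                  dimnames = list(NULL, rownames(ld)))
  structure(list(lbf = lbf, method = "SuSiE", credible_sets = sets,
                 converged = converged),
            class = "bf_decomposition")
}

#' Bayes factors for a region by either method
#'
#' Dispatches to [region_abf()] (`method = "abf"`) or [susie_rss()]
#' (`method = "susie"`). In SuSiE mode, when no credible set survives the
#' coverage/purity filter the single-signal ABF row is substituted
#' (`fallback` attribute set), so every testable region remains scorable
#' in both modes.
#'
#' @param region a [region_summary()].
#' @param ld an [ld_matrix()] aligned to `region` (SuSiE mode only).
#' @param method `"abf"` or `"susie"`.
#' @param prior an [effect_prior()] (used for ABF and the fallback row).
#' @param config a [susie_config()] (SuSiE mode).
#' @param fallback substitute the ABF row when SuSiE retains no signal;
#'   default TRUE.
#' @return a [bf_decomposition()].
#' @export
region_bf <- function(region, ld = NULL, method = c("abf", "susie"),
                      prior = effect_prior(), config = susie_config(),
                      fallback = TRUE) {
  method <- match.arg(method)
  if (method == "abf") return(region_abf(region, prior))
  if (is.null(ld)) stop_validation("SuSiE mode needs an LD matrix")
  bf <- susie_rss(region$z, ld, config)
  if (nrow(bf$lbf) == 0L && fallback) {
    bf <- region_abf(region, prior)
    attr(bf, "fallback") <- TRUE
  }
  bf
}

#' Read an externally computed per-signal log Bayes factor matrix
#'
#' Accepts the tabular layout produced by any fine-mapper that reports
#' per-signal, per-SNP log Bayes factors: one row per signal, one column
#' per SNP, header of snp ids.
#'
#' @param path delimited file.
#' @param method label stored on the decomposition; default `"SuSiE"`.
#' @return a [bf_decomposition()].
#' @export
read_lbf_table <- function(path, method = "SuSiE") {
  dt <- data.table::fread(path)
  m <- as.matrix(dt)
  bf_decomposition(m, method = method, converged = NA)
}
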
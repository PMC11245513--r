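#' Prior standard deviation of the causal effect
#'
#' The Wakefield approximate Bayes factor places a `N(0, W)` prior on the
#' true effect; `W = sd_cc^2` for case-control traits (log odds-ratio scale)
#' and `W = sd_quant^2` for quantitative traits (standardized scale). Neither
#' value is dictated by theory; the defaults are the conventional
#' coloc-family choices.
#'
#' @param sd_cc prior sd of the causal log odds ratio; default 0.2.
#' @param sd_quant prior sd of the standardized causal effect; default 0.15.
#' @export
effect_prior <- function(sd_cc = 0.2, sd_quant = 0.15) {
  if (sd_cc <= 0 || sd_quant <= 0) stop_validation("prior sds must be > 0")
  structure(list(sd_cc = sd_cc, sd_quant = sd_quant), class = "effect_prior")
}

#' Wakefield log approximate Bayes factor
#'
#' For an effect estimate `beta_hat` with sampling variance `V` (so
#' `z = beta_hat / sqrt(V)`) and a `N(0, W)` effect prior, the log Bayes
#' factor of "this SNP associated" versus the null is
#' `0.5 * (log(V / (V + W)) + z^2 * W / (V + W))`, i.e. the log ratio of the
#' marginal likelihoods `N(beta_hat; 0, V + W)` and `N(beta_hat; 0, V)`.
#'
#' Vectorized over `z` and `V`.
#'
#' @param z z-score(s), finite.
#' @param V sampling variance(s) of the effect estimate, > 0.
#' @param W prior effect variance, >= 0.
#' @return natural-log Bayes factor(s).
#' @export
wakefield_labf <- function(z, V, W) {
  if (any(V <= 0)) stop("V must be > 0")
  if (any(W < 0)) stop("W must be >= 0")
  if (!all(is.finite(z))) stop("z must be finite")
  r <- W / (V + W)
  0.5 * (log1p(-r) + z^2 * r)
}

#' Per-signal, per-SNP log Bayes factor decomposition
#'
#' @param lbf `L x Q` matrix of natural-log Bayes factors of "SNP j causal
#'   (in signal l)" versus "no causal variant"; column names are snp ids.
#' @param method `"ABF"` (single causal variant, L = 1) or `"SuSiE"`.
#' @param credible_sets list of integer index vectors, one per signal
#'   (SuSiE only).
#' @param converged logical convergence flag (SuSiE only).
#' @keywords internal
bf_decomposition <- function(lbf, method = c("ABF", "SuSiE"),
                             credible_sets = NULL, converged = NA) {
  method <- match.arg(method)
  lbf <- rbind(lbf)
  if (method == "ABF" && nrow(lbf) != 1L)
    stop_validation("ABF decompositions have exactly one signal row")
  if (!all(is.finite(lbf))) stop_validation("all lbf must be finite")
  structure(list(lbf = lbf, method = method,
                 credible_sets = credible_sets, converged = converged),
            class = "bf_decomposition")
}

#' @export
print.bf_decomposition <- function(x, ...) {
  cat(sprintf("<bf_decomposition> %s: %d signal(s) x %d SNPs\n",
              x$method, nrow(x$lbf), ncol(x$lbf)))
  invisible(x)
}

#' Sampling variance of the effect estimate
#'
#' `se^2` when standard errors are available; otherwise the standard
#' study-design approximation `1 / (2 maf (1-maf) n s (1-s))` for
#' case-control traits and `1 / (2 maf (1-maf) n)` for quantitative traits.
#'
#' @param region a [region_summary()].
#' @keywords internal
effect_variance <- function(region) {
  if (!is.null(region$se)) return(region$se^2)
  if (is.null(region$maf) || is.null(region$n))
    stop_validation("need either se or (maf, n) to form V")
  het <- 2 * region$maf * (1 - region$maf)
  if (region$trait_type == "cc") {
    if (is.null(region$s)) stop_validation("case-control fallback needs s")
    1 / (het * region$n * region$s * (1 - region$s))
  } else 1 / (het * region$n)
}

#' Single-causal-variant Bayes factors for a region
#'
#' Computes the Wakefield log approximate Bayes factor for every SNP under
#' the assumption of at most one causal variant in the region, giving an
#' `L = 1` [bf_decomposition()].
#'
#' @param region a [region_summary()] with z-scores (and `se`, or the
#'   `maf`/`n`/`s` fields needed for the variance fallback).
#' @param prior an [effect_prior()].
#' @return a `bf_decomposition` with `method = "ABF"`.
#' @export
region_abf <- function(region, prior = effect_prior()) {
  V <- effect_variance(region)
  W <- if (region$trait_type == "cc") prior$sd_cc^2 else prior$sd_quant^2
  lbf <- matrix(wakefield_labf(region$z, V, W), nrow = 1L,
                dimnames = list(NULL, region$snp_ids))
  bf_decomposition(lbf, method = "ABF")
}
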
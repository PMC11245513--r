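#' Prior probabilities over the hypothesis space
#'
#' In a region with `Q` SNPs and at most one causal variant there are
#' `Q + 1` configurations: no causal variant (prior mass `pn`), each of the
#' `Q - 1` non-query SNPs causal (mass `pa` each), or the query variant
#' causal (mass `pc`), under the constraint `pn + (Q-1) pa + pc = 1`. `pn`
#' is derived from the constraint.
#'
#' @param pa per-SNP prior probability that a given non-query SNP is causal.
#' @param pc prior probability that the query variant is causal.
#' @param Q number of SNPs in the region.
#' @return object of class `prior_set` with fields `pn`, `pa`, `pc`, `Q`.
#' @export
prior_set <- function(pa, pc, Q) {
  if (Q < 2L) stop_validation("Q must be >= 2")
  pn <- 1 - (Q - 1) * pa - pc
  # upper bound inclusive: pn rounds to exactly 1 in the degenerate
  # no-signal limit (pa, pc underflow-small)
  for (p in c(pn = pn, pa = pa, pc = pc))
    if (!is.finite(p) || p <= 0 || p > 1)
      stop_validation("priors must lie in (0, 1); got pn=", signif(pn, 4),
                      " pa=", signif(pa, 4), " pc=", signif(pc, 4))
  structure(list(pn = pn, pa = pa, pc = pc, Q = as.integer(Q)),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat(sprintf("<prior_set> Q=%d  pn=%.4g  pa=%.4g  pc=%.4g  (pc/pa=%.3g)\n",
              x$Q, x$pn, x$pa, x$pc, x$pc / x$pa))
  invisible(x)
}

#' Posterior probabilities of Hn, Ha, Hc for each signal
#'
#' For signal `l` with log Bayes factors `lbf[l, ]`, the unnormalized
#' hypothesis masses are `m_n = pn`, `m_a = pa * sum_{j != q} BF_j` and
#' `m_c = pc * BF_q`; posteriors are the normalized masses. All arithmetic
#' is on the log scale via log-sum-exp.
#'
#' @param bf a [bf_decomposition()].
#' @param priors a [prior_set()] with `Q` equal to the number of SNPs.
#' @param query_index 1-based index of the query variant.
#' @param trait_id,query_id optional labels carried into the result.
#' @return data.frame, one row per signal, with columns `trait_id`,
#'   `query_id`, `signal`, `ppHn`, `ppHa`, `ppHc`.
#' @export
region_posteriors <- function(bf, priors, query_index,
                              trait_id = NA_character_,
                              query_id = NULL) {
  if (!inherits(priors, "prior_set")) stop_validation("priors must be a prior_set")
  Q <- ncol(bf$lbf)
  if (priors$Q != Q) stop_validation("priors$Q (", priors$Q,
                                     ") != number of SNPs (", Q, ")")
  if (is.na(query_index) || query_index < 1L || query_index > Q)
    stop_validation("query_index out of range")
  L <- nrow(bf$lbf)
  out <- matrix(NA_real_, L, 3L)
  for (l in seq_len(L)) {
    lbf <- bf$lbf[l, ]
    lm <- c(log(priors$pn),
            log(priors$pa) + logsumexp(lbf[-query_index]),
            log(priors$pc) + lbf[query_index])
    out[l, ] <- exp(lm - logsumexp(lm))
  }
  data.frame(trait_id = trait_id,
             query_id = query_id %||% colnames(bf$lbf)[query_index] %||%
               NA_character_,
             signal = seq_len(L),
             ppHn = out[, 1L], ppHa = out[, 2L], ppHc = out[, 3L])
}

#' Trait-level hypothesis call from per-signal posteriors
#'
#' Each signal is labelled Hc when `ppHc > t_hc`, else Hn when
#' `ppHn > t_hn`, else Ha. The trait takes the first label present in the
#' ranking Hc > Hn > Ha: one Hc signal suffices to call the trait Hc; a
#' trait with Hn but no Hc signals is called Hn (conservative about ruling
#' out pleiotropy); otherwise Ha, reporting the signal with the minimum
#' ppHa. Among several Hc signals the one with maximal ppHc is reported.
#'
#' @param results data.frame from [region_posteriors()] (>= 1 row).
#' @param t_hc ppHc threshold for calling Hc; default 0.6.
#' @param t_hn ppHn threshold for calling Hn; default 0.2.
#' @return one-row data.frame: `call`, `signal`, `ppHn`, `ppHa`, `ppHc`,
#'   `t_hc`, `t_hn`.
#' @export
call_trait <- function(results, t_hc = 0.6, t_hn = 0.2) {
  if (is.null(results) || nrow(results) == 0L)
    stop_validation("call_trait needs at least one signal")
  lab <- ifelse(results$ppHc > t_hc, "Hc",
                ifelse(results$ppHn > t_hn, "Hn", "Ha"))
  if (any(lab == "Hc")) {
    i <- which(lab == "Hc")[which.max(results$ppHc[lab == "Hc"])]
    call <- "Hc"
  } else if (any(lab == "Hn")) {
    i <- which(lab == "Hn")[which.max(results$ppHn[lab == "Hn"])]
    call <- "Hn"
  } else {
    i <- which.min(results$ppHa)
    call <- "Ha"
  }
  data.frame(call = call, signal = results$signal[i],
             ppHn = results$ppHn[i], ppHa = results$ppHa[i],
             ppHc = results$ppHc[i], t_hc = t_hc, t_hn = t_hn)
}

#' Internal false discovery rate estimate
#'
#' Estimates the FDR among traits called at threshold `t` as
#' `1 - mean(ppHc | ppHc > t)`: if the posteriors are calibrated, the
#' expected fraction of false Hc calls. Returns `NA` when no value
#' exceeds `t`.
#'
#' @param pphc vector of ppHc values in \[0, 1\].
#' @param t calling threshold; default 0.6.
#' @export
estimate_fdr <- function(pphc, t = 0.6) {
  if (any(pphc < 0 | pphc > 1, na.rm = TRUE))
    stop_validation("ppHc values must lie in [0, 1]")
  sel <- pphc[!is.na(pphc) & pphc > t]
  if (length(sel) == 0L) return(NA_real_)
  1 - mean(sel)
}
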
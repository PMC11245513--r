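#' Bonferroni p-value threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests, >= 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1L || is.na(m) || m < 1) stop_validation("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha in (0, 1)")
  alpha / m
}

#' Conventional p-value-threshold PheWAS
#'
#' Tests the query variant's p-value per trait against a multiplicity-
#' corrected threshold: Benjamini-Hochberg step-up (largest `k` with
#' `p_(k) <= k alpha / m`) or Bonferroni (`alpha / m`).
#'
#' @param pvals query-variant p-values, one per trait, in (0, 1].
#' @param method `"bh"` or `"bonferroni"`.
#' @param alpha target FDR (BH) or FWER (Bonferroni); default 0.05.
#' @return list: `reject` (logical per trait), `threshold` (realized
#'   p-value cutoff), `method`, `alpha`.
#' @export
conventional_phewas <- function(pvals, method = c("bh", "bonferroni"),
                                alpha = 0.05) {
  method <- match.arg(method)
  if (length(pvals) == 0L) stop_validation("empty p-value vector")
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE))
    stop_validation("p-values must lie in (0, 1]")
  m <- length(pvals)
  if (method == "bonferroni") {
    thr <- bonferroni_threshold(alpha, m)
  } else {
    ps <- sort(pvals)
    k <- which(ps <= seq_len(m) * alpha / m)
    thr <- if (length(k)) ps[max(k)] else 0
  }
  list(reject = !is.na(pvals) & pvals <= thr, threshold = thr,
       method = method, alpha = alpha)
}

#' Per-signal posteriors for a whole dataset under fixed priors
#'
#' Applies the region posterior computation to every (trait, signal) row
#' of a statistics table using one shared (pa, pc); `pn` follows from each
#' region's `Q` through the prior-sum constraint.
#'
#' @param stats data.frame of [region_stats()] rows.
#' @param pa,pc fixed per-SNP and query-variant prior probabilities.
#' @return data.frame: `trait_id`, `signal`, `ppHn`, `ppHa`, `ppHc`.
#' @export
score_signals <- function(stats, pa, pc) {
  pn <- 1 - (stats$Q - 1) * pa - pc
  if (any(pn <= 0)) stop_validation("pn <= 0: priors invalid for this Q")
  t0 <- log(pn)
  t1 <- log(pa) + stats$S
  t2 <- log(pc) + stats$lq
  lm <- lse3(t0, t1, t2)
  data.frame(trait_id = stats$trait_id, signal = stats$signal,
             ppHn = exp(t0 - lm), ppHa = exp(t1 - lm), ppHc = exp(t2 - lm))
}

#' Trait-level calls from per-signal posteriors
#'
#' Vectorized [call_trait()] over traits: signals are labelled by the
#' thresholds, then each trait takes the first label present in the
#' ranking Hc > Hn > Ha, reporting the maximal-ppHc Hc signal, the
#' maximal-ppHn Hn signal, or the minimal-ppHa Ha signal respectively.
#'
#' @param posteriors data.frame with `trait_id`, `signal`, `ppHn`,
#'   `ppHa`, `ppHc` (from [score_signals()] or a chain summary).
#' @param t_hc,t_hn calling thresholds; defaults 0.6 and 0.2.
#' @return data.frame, one row per trait: `trait_id`, `call`, `signal`,
#'   `ppHn`, `ppHa`, `ppHc`.
#' @export
trait_calls <- function(posteriors, t_hc = 0.6, t_hn = 0.2) {
  dt <- data.table::as.data.table(posteriors)
  lab <- ifelse(dt$ppHc > t_hc, "Hc", ifelse(dt$ppHn > t_hn, "Hn", "Ha"))
  dt[, lab := lab]
  pick <- function(signal, ppHc, ppHn, ppHa, lab) {
    i <- if (any(lab == "Hc")) which(lab == "Hc")[which.max(ppHc[lab == "Hc"])]
    else if (any(lab == "Hn")) which(lab == "Hn")[which.max(ppHn[lab == "Hn"])]
    else which.min(ppHa)
    list(call = lab[i], signal = signal[i], ppHn = ppHn[i], ppHa = ppHa[i],
         ppHc = ppHc[i])
  }
  out <- dt[, pick(signal, ppHc, ppHn, ppHa, lab), by = "trait_id"]
  as.data.frame(out)
}

#' Evaluate calls against simulated truth
#'
#' @param calls data.frame with `trait_id` and `call`; `call` is `"Hc"`
#'   for a positive scan call (or logical/`"associated"` for the
#'   conventional comparator).
#' @param truth data.frame with `trait_id` and `truth` (one of the five
#'   simulation classes); ids must match `calls` one-to-one.
#' @return list of class `eval_report`: `confusion` (truth x call table),
#'   `sensitivity` (per truth class, fraction called positive),
#'   `fdr` (fraction of positive calls whose truth is Hn/Ha/Ha2),
#'   `n` (dataset size).
#' @export
evaluate_calls <- function(calls, truth) {
  if (is.logical(calls$call)) calls$call <- ifelse(calls$call, "Hc", "Hn")
  calls$call[calls$call == "associated"] <- "Hc"
  i <- match(truth$trait_id, calls$trait_id)
  if (anyNA(i) || nrow(calls) != nrow(truth))
    stop_validation("calls and truth must cover the same trait ids")
  call <- calls$call[i]
  confusion <- table(truth = truth$truth, call = call)
  positive <- call == "Hc"
  sens <- tapply(positive, truth$truth, mean)
  n_pos <- sum(positive)
  fdr <- if (n_pos == 0L) NA_real_
  else sum(positive & truth$truth %in% c("Hn", "Ha", "Ha2")) / n_pos
  structure(list(confusion = confusion, sensitivity = sens, fdr = fdr,
                 n = nrow(truth)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$confusion)
  cat(sprintf("true-label FDR: %s\n",
              ifelse(is.na(x$fdr), "NA (no positive calls)",
                     sprintf("%.4f", x$fdr))))
  invisible(x)
}

#' Bookkeeping for benchmark class counts
#'
#' Validates a named class-count vector and reports the total and the
#' percentage of traits whose truth involves the query variant (classes
#' `Hc` and `Hc2`), the quantity varied in robustness experiments.
#'
#' @param class_counts named nonnegative counts over a subset of
#'   `Hn`, `Ha`, `Ha2`, `Hc`, `Hc2`.
#' @return list: `counts`, `total`, `hc_percent`.
#' @export
benchmark_class_counts <- function(class_counts) {
  known <- c("Hn", "Ha", "Ha2", "Hc", "Hc2")
  if (is.null(names(class_counts)) || !all(names(class_counts) %in% known))
    stop_validation("class counts must be named with ",
                    paste(known, collapse = "/"))
  if (any(class_counts < 0)) stop_validation("counts must be >= 0")
  total <- sum(class_counts)
  hc <- sum(class_counts[names(class_counts) %in% c("Hc", "Hc2")])
  list(counts = class_counts, total = total,
       hc_percent = if (total > 0) 100 * hc / total else NA_real_)
}

#' End-to-end scan of a simulated benchmark dataset
#'
#' Convenience wrapper running Bayes factors, priors (fixed or
#' hierarchical), scoring and trait-level calling on a
#' [build_benchmark_dataset()] result.
#'
#' @param dataset a `phescan_dataset`.
#' @param method Bayes factor mode, `"abf"` or `"susie"`.
#' @param priors `"hierarchical"` or a numeric `c(pa, pc)` pair for fixed
#'   priors.
#' @param use_covariate include the simulated covariate in the
#'   hierarchical model; default FALSE.
#' @param mcmc an [mcmc_config()].
#' @param t_hc,t_hn calling thresholds.
#' @param susie a [susie_config()] (SuSiE mode only).
#' @return list: `stats`, `posteriors`, `calls`, `chain` (NULL for fixed
#'   priors), `internal_fdr` (the estimate at `t_hc`), `report`
#'   ([evaluate_calls()] against the dataset truth).
#' @export
run_scan <- function(dataset, method = c("abf", "susie"),
                     priors = "hierarchical", use_covariate = FALSE,
                     mcmc = mcmc_config(), t_hc = 0.6, t_hn = 0.2,
                     susie = susie_config()) {
  method <- match.arg(method)
  stats <- if (method == "abf") dataset_abf_stats(dataset)
  else dataset_susie_stats(dataset, config = susie)
  chain <- NULL
  if (identical(priors, "hierarchical")) {
    chain <- mcmc_run(stats, mcmc, use_covariate = use_covariate)
    posteriors <- chain$posteriors
  } else {
    posteriors <- score_signals(stats, pa = priors[1L], pc = priors[2L])
  }
  calls <- trait_calls(posteriors, t_hc = t_hc, t_hn = t_hn)
  internal_fdr <- estimate_fdr(calls$ppHc, t_hc)
  report <- evaluate_calls(calls, dataset$truth)
  list(stats = stats, posteriors = posteriors, calls = calls, chain = chain,
       internal_fdr = internal_fdr, report = report)
}
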
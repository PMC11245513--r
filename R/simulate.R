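#' Parametric LD model
#'
#' Stands in for reference-panel haplotypes: either a single AR1
#' correlation band (`r[i,j] = rho^|i-j|`) or a block-diagonal matrix of
#' AR1 blocks, which concentrates LD locally the way recombination
#' hotspots partition real genomes. Minor allele frequencies are drawn
#' uniformly from `maf_range` (floor 0.01, matching the usual simulation
#' practice of discarding rarer variants).
#'
#' @param kind `"blockwise"` (default) or `"ar1"`.
#' @param rho within-block (or global) AR1 decay; default 0.95.
#' @param block_size SNPs per block for `"blockwise"`; default 25.
#' @param maf_range range of the uniform MAF distribution.
#' @export
ld_model <- function(kind = c("blockwise", "ar1"), rho = 0.95,
                     block_size = 25L, maf_range = c(0.01, 0.5)) {
  kind <- match.arg(kind)
  if (abs(rho) >= 1) stop_validation("|rho| must be < 1")
  structure(list(kind = kind, rho = rho, block_size = as.integer(block_size),
                 maf_range = maf_range), class = "ld_model")
}

ar1_matrix <- function(Q, rho) rho^abs(outer(seq_len(Q), seq_len(Q), "-"))

#' Simulate an LD matrix and MAF vector
#'
#' @param Q number of SNPs (>= 2).
#' @param model an [ld_model()].
#' @param seed optional RNG seed (for the MAF draw).
#' @return list with `ld` (an [ld_matrix()]) and `maf`.
#' @export
simulate_ld <- function(Q, model = ld_model(), seed = NULL) {
  if (Q < 2L) stop_validation("Q must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  r <- if (model$kind == "ar1") {
    ar1_matrix(Q, model$rho)
  } else {
    m <- matrix(0, Q, Q)
    starts <- seq(1L, Q, by = model$block_size)
    for (s in starts) {
      e <- min(s + model$block_size - 1L, Q)
      m[s:e, s:e] <- ar1_matrix(e - s + 1L, model$rho)
    }
    m
  }
  maf <- stats::runif(Q, model$maf_range[1L], model$maf_range[2L])
  pos <- 1e6 + 2000 * seq_len(Q)
  ids <- sprintf("1_%d_A_G", as.integer(pos))
  # closed-form AR1 correlation is already PSD; only shrink the blockwise
  # composite, whose assembly can brush zero eigenvalues at finite precision
  list(ld = ld_matrix(r, ids, regularize = (model$kind == "blockwise")),
       maf = maf)
}

#' One simulated trait scenario
#'
#' Truth classes follow the benchmark design: `Hn` no causal variant;
#' `Ha`/`Ha2` one/two causal variants, none the query variant; `Hc` the
#' query variant causal; `Hc2` the query variant plus one other causal.
#'
#' @param truth one of `"Hn"`, `"Ha"`, `"Ha2"`, `"Hc"`, `"Hc2"`.
#' @param Q region size.
#' @param query_index 1-based query variant index.
#' @param causal_indices integer vector of causal SNP indices (0, 1 or 2
#'   entries as dictated by `truth`).
#' @param causal_log_ors causal log odds ratios, one per causal index.
#' @param n_cases,n_controls study design; defaults 10000/10000.
#' @export
sim_scenario <- function(truth = c("Hn", "Ha", "Ha2", "Hc", "Hc2"), Q,
                         query_index, causal_indices = integer(0),
                         causal_log_ors = numeric(0),
                         n_cases = 10000L, n_controls = 10000L) {
  truth <- match.arg(truth)
  need <- c(Hn = 0L, Ha = 1L, Ha2 = 2L, Hc = 1L, Hc2 = 2L)[[truth]]
  if (length(causal_indices) != need)
    stop_validation(truth, " needs ", need, " causal variant(s)")
  if (length(causal_log_ors) != need)
    stop_validation("need one log OR per causal variant")
  if (any(causal_indices < 1L | causal_indices > Q))
    stop_validation("causal index out of range")
  qin <- query_index %in% causal_indices
  if (truth %in% c("Hc", "Hc2") && !qin)
    stop_validation(truth, " requires the query variant among the causals")
  if (truth %in% c("Ha", "Ha2") && qin)
    stop_validation(truth, " excludes the query variant from the causals")
  structure(list(truth = truth, Q = as.integer(Q),
                 query_index = as.integer(query_index),
                 causal_indices = as.integer(causal_indices),
                 causal_log_ors = causal_log_ors,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls)),
            class = "sim_scenario")
}

#' Simulate regional case-control summary statistics
#'
#' Multivariate-normal z-score model: with per-SNP non-centrality
#' `lambda_m = gamma_m * sqrt(2 f_m (1-f_m) n s (1-s))` at causal SNPs
#' (0 elsewhere), the expected z-vector is `R lambda` and the observed
#' vector is drawn `z ~ MVN(R lambda, R)`. Standard errors come from the
#' MAF-based variance approximation, `beta = z * se`.
#'
#' @param scenario a [sim_scenario()].
#' @param ld an [ld_matrix()] of dimension `Q`.
#' @param maf MAF vector of length `Q`.
#' @param seed optional RNG seed.
#' @param trait_id trait label.
#' @return a [region_summary()] with attribute `truth`.
#' @export
simulate_region <- function(scenario, ld, maf, seed = NULL,
                            trait_id = "sim_trait") {
  Q <- scenario$Q
  if (nrow(ld) != Q || length(maf) != Q)
    stop_validation("ld/maf dimensions do not match scenario Q")
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_cases + scenario$n_controls
  s <- scenario$n_cases / n
  se <- 1 / sqrt(2 * maf * (1 - maf) * n * s * (1 - s))
  lambda <- rep(0, Q)
  lambda[scenario$causal_indices] <-
    scenario$causal_log_ors / se[scenario$causal_indices]
  R <- unclass(ld)
  mu <- drop(R %*% lambda)
  C <- chol(R)
  z <- mu + drop(crossprod(C, stats::rnorm(Q)))
  out <- region_summary(snp_ids = rownames(ld), beta = z * se, se = se,
                        maf = maf, n = n, s = s, trait_type = "cc",
                        query_index = scenario$query_index,
                        trait_id = trait_id)
  attr(out, "truth") <- scenario$truth
  out
}

n_causal <- c(Hn = 0L, Ha = 1L, Ha2 = 2L, Hc = 1L, Hc2 = 2L)

#' Simulate per-trait genetic correlation covariates
#'
#' Traits whose truth involves the query variant (`Hc`, `Hc2`) draw their
#' genetic correlation with the primary trait from a distribution shifted
#' towards high values (truncated normal, mean 0.5), while `Hn`/`Ha`/`Ha2`
#' traits draw from a symmetric null distribution (truncated normal,
#' mean 0); both truncated to \[-1, 1\] with sd 0.25.
#'
#' @param truth character vector of truth labels.
#' @param seed optional RNG seed.
#' @return data.frame with columns `trait_id` (running index when labels
#'   are unnamed), `truth`, `rg`.
#' @export
simulate_rg <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mean_rg <- ifelse(truth %in% c("Hc", "Hc2"), 0.5, 0)
  rg <- rtrunc_norm(length(truth), mean_rg, 0.25, -1, 1)
  data.frame(trait_id = names(truth) %||% as.character(seq_along(truth)),
             truth = truth, rg = rg)
}

# vectorized rejection sampler for the truncated normal; fine for the
# mild truncations used here (acceptance ~ 1)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  mu <- rep_len(mean, n)
  x <- stats::rnorm(n, mu, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mu[bad], sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Build a benchmark dataset with known truth
#'
#' Simulates one LD template and `sum(class_counts)` regional traits of
#' the five truth classes, with the query variant sampled uniformly per
#' trait and causal log odds ratios drawn
#' `|gamma| ~ U(effect_range)` with random sign. Two-causal scenarios
#' resample until the causal pair has `|r| < 0.95` so the configurations
#' stay distinguishable. Stored compactly as a z-score matrix plus the
#' shared template; use [dataset_region()] to materialize any single
#' trait as a [region_summary()].
#'
#' @param class_counts named counts for `Hn`, `Ha`, `Ha2`, `Hc`, `Hc2`
#'   (default: the 1/10-scale benchmark 8805/470/470/628/628).
#' @param Q SNPs per region; default 200.
#' @param model an [ld_model()].
#' @param effect_range magnitude range of causal log odds ratios.
#' @param n_cases,n_controls study design; defaults 10000/10000.
#' @param with_rg simulate the genetic-correlation covariate; default TRUE.
#' @param seed RNG seed; default 1.
#' @return object of class `phescan_dataset`: `z` (traits x Q matrix),
#'   `ld`, `maf`, `se`, `n`, `s`, `Q`, and `truth` (data.table:
#'   `trait_id`, `truth`, `query_index`, causal indices/effects, `rg`).
#' @export
build_benchmark_dataset <- function(class_counts = c(Hn = 8805, Ha = 470,
                                                     Ha2 = 470, Hc = 628,
                                                     Hc2 = 628),
                                    Q = 200L, model = ld_model(),
                                    effect_range = c(0.08, 0.25),
                                    n_cases = 10000L, n_controls = 10000L,
                                    with_rg = TRUE, seed = 1L) {
  if (any(class_counts < 0)) stop_validation("class counts must be >= 0")
  if (is.null(names(class_counts)))
    names(class_counts) <- c("Hn", "Ha", "Ha2", "Hc", "Hc2")
  set.seed(seed)
  sim <- simulate_ld(Q, model)
  R <- unclass(sim$ld)
  n_traits <- sum(class_counts)
  truth_lab <- rep(names(class_counts), class_counts)
  n <- n_cases + n_controls
  s <- n_cases / n
  se <- 1 / sqrt(2 * sim$maf * (1 - sim$maf) * n * s * (1 - s))
  empty <- function() rep(NA_integer_, n_traits)
  tt <- data.table::data.table(
    trait_id = sprintf("t%06d", seq_len(n_traits)), truth = truth_lab,
    query_index = sample.int(Q, n_traits, replace = TRUE),
    causal1 = empty(), causal2 = empty(),
    log_or1 = rep(NA_real_, n_traits), log_or2 = rep(NA_real_, n_traits))
  draw_or <- function(k) sample(c(-1, 1), k, TRUE) *
    stats::runif(k, effect_range[1L], effect_range[2L])
  Lam <- matrix(0, n_traits, Q)
  for (i in seq_len(n_traits)) {
    k <- n_causal[[truth_lab[i]]]
    if (k == 0L) next
    q <- tt$query_index[i]
    repeat {
      ci <- if (truth_lab[i] == "Hc") q
      else if (truth_lab[i] == "Hc2") c(q, sample(seq_len(Q)[-q], 1L))
      else sample(seq_len(Q)[-q], k)
      if (k < 2L || abs(R[ci[1L], ci[2L]]) < 0.95) break
    }
    go <- draw_or(k)
    tt$causal1[i] <- ci[1L]
    tt$log_or1[i] <- go[1L]
    if (k == 2L) { tt$causal2[i] <- ci[2L]; tt$log_or2[i] <- go[2L] }
    Lam[i, ci] <- go / se[ci]
  }
  mu <- Lam %*% R
  C <- chol(R)
  z <- mu + matrix(stats::rnorm(n_traits * Q), n_traits, Q) %*% C
  tt$rg <- if (with_rg) simulate_rg(truth_lab)$rg else 0
  structure(list(z = z, ld = sim$ld, maf = sim$maf, se = se, n = n, s = s,
                 Q = as.integer(Q), truth = tt,
                 class_counts = class_counts),
            class = "phescan_dataset")
}

#' @export
print.phescan_dataset <- function(x, ...) {
  cat(sprintf("<phescan_dataset> %d traits x %d SNPs\n", nrow(x$z), x$Q))
  print(x$class_counts)
  invisible(x)
}

#' Materialize one benchmark trait as a region summary
#'
#' @param dataset a [build_benchmark_dataset()] result.
#' @param i trait row index or trait id.
#' @return a [region_summary()] with attribute `truth`.
#' @export
dataset_region <- function(dataset, i) {
  if (is.character(i)) i <- match(i, dataset$truth$trait_id)
  z <- dataset$z[i, ]
  out <- region_summary(snp_ids = rownames(dataset$ld), beta = z * dataset$se,
                        se = dataset$se, maf = dataset$maf, n = dataset$n,
                        s = dataset$s, trait_type = "cc",
                        query_index = dataset$truth$query_index[i],
                        trait_id = dataset$truth$trait_id[i])
  attr(out, "truth") <- dataset$truth$truth[i]
  out
}

#' Write a benchmark dataset to a directory
#'
#' One summary table per trait, the shared LD template with its id
#' sidecar, and a truth table (including the covariate), mirroring the
#' formats read by [read_gwas_table()], [read_ld_matrix()] and
#' [read_covariate_table()].
#'
#' @param dataset a `phescan_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_benchmark_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ld_matrix(dataset$ld, file.path(dir, "ld.tsv"))
  data.table::fwrite(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t")
  for (i in seq_len(nrow(dataset$truth)))
    write_gwas_table(dataset_region(dataset, i),
                     file.path(dir, paste0(dataset$truth$trait_id[i], ".tsv")))
  invisible(dir)
}

#' Single-causal-variant Bayes factor statistics for a whole dataset
#'
#' Vectorized [region_abf()] + [region_stats()] over every trait: returns
#' the per-trait hierarchical-likelihood statistics (`S`, `lq`) and, on
#' request, the full log Bayes factor matrix.
#'
#' @param dataset a `phescan_dataset`.
#' @param prior an [effect_prior()].
#' @param keep_lbf also return the traits x Q lbf matrix; default FALSE.
#' @return data.frame of [region_stats()] rows (signal = 1 throughout),
#'   with the covariate in `x`; lbf matrix in attribute `"lbf"` when
#'   requested.
#' @export
dataset_abf_stats <- function(dataset, prior = effect_prior(),
                              keep_lbf = FALSE) {
  W <- prior$sd_cc^2
  V <- dataset$se^2
  r <- W / (V + W)
  nt <- nrow(dataset$z)
  lbf <- 0.5 * (matrix(log1p(-r), nt, dataset$Q, byrow = TRUE) +
                  dataset$z^2 * matrix(r, nt, dataset$Q, byrow = TRUE))
  qi <- cbind(seq_len(nt), dataset$truth$query_index)
  lq <- lbf[qi]
  tmp <- lbf
  tmp[qi] <- -Inf
  S <- row_logsumexp(tmp)
  out <- data.frame(trait_id = dataset$truth$trait_id, signal = 1L,
                    S = S, lq = lq, Q = dataset$Q, x = dataset$truth$rg)
  if (keep_lbf) attr(out, "lbf") <- lbf
  out
}

#' SuSiE Bayes factor statistics for a whole dataset
#'
#' Runs [susie_rss()] per trait against the shared LD template (with ABF
#' fallback for traits where no credible set is retained) and stacks the
#' per-signal statistics.
#'
#' @inheritParams dataset_abf_stats
#' @param config a [susie_config()].
#' @return data.frame of [region_stats()] rows, possibly several per trait.
#' @export
dataset_susie_stats <- function(dataset, config = susie_config(),
                                prior = effect_prior()) {
  out <- vector("list", nrow(dataset$z))
  for (i in seq_len(nrow(dataset$z))) {
    region <- dataset_region(dataset, i)
    bf <- region_bf(region, dataset$ld, method = "susie",
                    prior = prior, config = config)
    out[[i]] <- region_stats(bf, dataset$truth$query_index[i],
                             trait_id = dataset$truth$trait_id[i],
                             x = dataset$truth$rg[i])
  }
  do.call(rbind, out)
}
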
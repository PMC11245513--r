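test_that("bonferroni_threshold arithmetic and validation", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.1, 10), 0.01)
  expect_equal(signif(bonferroni_threshold(0.05, 110000), 3), 4.55e-7)
  expect_error(bonferroni_threshold(0.05, 0), class = "phescan_validation_error")
})

test_that("conventional_phewas implements BH step-up and Bonferroni", {
  p <- c(0.001, 0.011, 0.02, 0.8)
  res <- conventional_phewas(p, "bh", alpha = 0.05)
  expect_equal(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$threshold, 0.02)   # cutoff realized at k = 3 (3*0.05/4 = 0.0375)
  expect_equal(res$reject, oracle_bh(p, 0.05))

  expect_true(conventional_phewas(0.04, "bonferroni", 0.05)$reject)
  expect_false(any(conventional_phewas(rep(1, 5), "bh")$reject))
  expect_false(any(conventional_phewas(rep(1, 5), "bonferroni")$reject))
  expect_error(conventional_phewas(numeric(0)),
               class = "phescan_validation_error")
  expect_error(conventional_phewas(c(0.1, 0)),
               class = "phescan_validation_error")

  # property: BH rejections are a superset of Bonferroni rejections
  set.seed(15)
  for (i in 1:20) {
    p <- runif(50)^sample(1:4, 1L)
    bh <- conventional_phewas(p, "bh")$reject
    bf <- conventional_phewas(p, "bonferroni")$reject
    expect_true(all(!bf | bh))
    expect_equal(bh, oracle_bh(p, 0.05))
  }
})

test_that("evaluate_calls tallies the confusion matrix like a naive loop", {
  calls <- data.frame(trait_id = sprintf("t%02d", 1:8),
                      call = c("Hc", "Hn", "Hc", "Ha", "Hn", "Hc", "Hn",
                               "Hc"))
  truth <- data.frame(trait_id = sprintf("t%02d", 1:8),
                      truth = c("Hc", "Hn", "Hn", "Ha", "Hc", "Hc2", "Ha2",
                                "Ha"))
  rep <- evaluate_calls(calls, truth)
  # naive loop oracle
  n_pos <- 0L; n_fp <- 0L
  sens_num <- c(); sens_den <- c()
  for (i in 1:8) {
    pos <- calls$call[i] == "Hc"
    if (pos) {
      n_pos <- n_pos + 1L
      if (truth$truth[i] %in% c("Hn", "Ha", "Ha2")) n_fp <- n_fp + 1L
    }
  }
  expect_equal(rep$fdr, n_fp / n_pos)
  expect_equal(unname(rep$sensitivity[["Hc"]]), 1 / 2)  # t01 yes, t05 no
  expect_equal(sum(rep$confusion), 8L)

  # perfect calls and worst case
  perfect <- data.frame(trait_id = truth$trait_id,
                        call = ifelse(truth$truth %in% c("Hc", "Hc2"),
                                      "Hc", truth$truth))
  perfect$call[perfect$call %in% c("Ha2")] <- "Ha"
  repP <- evaluate_calls(perfect, truth)
  expect_equal(repP$fdr, 0)
  expect_equal(unname(repP$sensitivity[["Hc"]]), 1)
  all_hn <- data.frame(trait_id = sprintf("x%d", 1:4), truth = "Hn")
  all_hc <- data.frame(trait_id = sprintf("x%d", 1:4), call = "Hc")
  expect_equal(evaluate_calls(all_hc, all_hn)$fdr, 1)

  expect_error(evaluate_calls(calls[1:7, ], truth),
               class = "phescan_validation_error")
})

test_that("class-count bookkeeping validates and summarizes", {
  bb <- benchmark_class_counts(c(Hn = 88048, Ha = 4700, Ha2 = 4700,
                                 Hc = 6276, Hc2 = 6276))
  expect_equal(bb$total, 110000)
  varied <- benchmark_class_counts(c(Hn = 88048, Ha = 4700, Hc = 2000))
  expect_equal(signif(varied$hc_percent, 3), 2.11)
  expect_error(benchmark_class_counts(c(bogus = 3)),
               class = "phescan_validation_error")
})

test_that("score_signals matches region_posteriors row by row", {
  ds <- build_benchmark_dataset(c(Hn = 30, Ha = 5, Ha2 = 5, Hc = 10,
                                  Hc2 = 5), Q = 25L, seed = 16)
  st <- dataset_abf_stats(ds)
  pa <- 0.81 / 24; pc <- 0.091
  sc <- score_signals(st, pa, pc)
  for (i in c(2L, 31L, 50L)) {
    region <- dataset_region(ds, i)
    ref <- region_posteriors(region_abf(region), prior_set(pa, pc, 25L),
                             region$query_index)
    expect_equal(sc$ppHc[i], ref$ppHc, tolerance = 1e-10)
    expect_equal(sc$ppHn[i], ref$ppHn, tolerance = 1e-10)
  }
})

test_that("the command-line interface runs the pipeline end to end", {
  dir <- withr::local_tempdir()
  data_dir <- file.path(dir, "data")
  expect_equal(phescan_cli(c("simulate", "--out", data_dir, "--counts",
                             "40,5,5,8,8", "--q", "30", "--seed", "4")), 0L)
  expect_true(file.exists(file.path(data_dir, "truth.tsv")))

  stats_f <- file.path(dir, "stats.tsv")
  expect_equal(phescan_cli(c("bf", "--data", data_dir, "--method", "abf",
                             "--out", stats_f)), 0L)
  expect_true(file.exists(paste0(stats_f, ".json")))

  chain_f <- file.path(dir, "chain.tsv")
  expect_equal(phescan_cli(c("fit-priors", "--stats", stats_f, "--out",
                             chain_f, "--n-iter", "1000", "--thin", "10",
                             "--seed", "2")), 0L)
  post_f <- file.path(dir, "post.tsv")
  expect_equal(phescan_cli(c("score", "--stats", stats_f, "--priors-from",
                             chain_f, "--out", post_f)), 0L)
  post_fixed_f <- file.path(dir, "post_fixed.tsv")
  expect_equal(phescan_cli(c("score", "--stats", stats_f, "--fixed-priors",
                             "0.001,0.05", "--out", post_fixed_f)), 0L)
  calls_f <- file.path(dir, "calls.tsv")
  expect_equal(phescan_cli(c("call", "--posteriors", post_f, "--out",
                             calls_f)), 0L)
  eval_f <- file.path(dir, "eval.json")
  expect_equal(phescan_cli(c("evaluate", "--calls", calls_f, "--truth",
                             file.path(data_dir, "truth.tsv"), "--out",
                             eval_f)), 0L)
  expect_true(file.exists(eval_f))

  classic_f <- file.path(dir, "classic.tsv")
  expect_equal(phescan_cli(c("phewas-classic", "--data", data_dir,
                             "--method", "bh", "--out", classic_f)), 0L)
  cj <- jsonlite::read_json(paste0(classic_f, ".json"))
  expect_true(cj$threshold >= 0)

  # validation failures surface as exit code 2
  expect_equal(suppressMessages(phescan_cli(c("score", "--stats", stats_f))),
               2L)
  expect_equal(suppressMessages(phescan_cli(c("nonsense"))), 2L)
})
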
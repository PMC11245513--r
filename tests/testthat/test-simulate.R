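test_that("simulate_ld produces valid matrices with closed forms", {
  # independence limit
  s0 <- simulate_ld(10L, ld_model(kind = "ar1", rho = 0), seed = 1)
  expect_equal(unclass(s0$ld), diag(10L), ignore_attr = TRUE)

  # exact AR1 band
  s1 <- simulate_ld(20L, ld_model(kind = "ar1", rho = 0.9), seed = 2)
  expect_equal(unclass(s1$ld),
               0.9^abs(outer(1:20, 1:20, "-")), ignore_attr = TRUE)
  expect_true(all(s1$maf > 0.01 & s1$maf <= 0.5))

  # blockwise: PSD after regularization, block structure respected
  s2 <- simulate_ld(60L, ld_model(kind = "blockwise", rho = 0.95,
                                  block_size = 20L), seed = 3)
  expect_gte(min(eigen(unclass(s2$ld), symmetric = TRUE,
                       only.values = TRUE)$values), 0)
  expect_equal(unclass(s2$ld)[1L, 21L], 0)
})

test_that("sim_scenario validates truth/causal consistency", {
  expect_s3_class(sim_scenario("Hc", 10L, 3L, 3L, 0.2), "sim_scenario")
  expect_error(sim_scenario("Hc", 10L, 3L, 4L, 0.2), "query",
               class = "phescan_validation_error")
  expect_error(sim_scenario("Ha", 10L, 3L, 3L, 0.2), "excludes",
               class = "phescan_validation_error")
  expect_error(sim_scenario("Ha2", 10L, 3L, c(4L, 50L), c(0.2, 0.2)),
               "range", class = "phescan_validation_error")
  expect_error(sim_scenario("Hn", 10L, 3L, 5L, 0.2), "0 causal",
               class = "phescan_validation_error")
})

test_that("null traits are calibrated and p-values uniform", {
  Q <- 50L
  sim <- simulate_ld(Q, ld_model(kind = "blockwise", rho = 0.9,
                                 block_size = 10L), seed = 4)
  sc <- sim_scenario("Hn", Q, 1L)
  set.seed(5)
  reps <- 1000L
  zs <- t(vapply(seq_len(reps), function(i)
    simulate_region(sc, sim$ld, sim$maf)$z, numeric(Q)))
  expect_lt(max(abs(colMeans(zs))), 4 / sqrt(reps))
  # KS needs independent draws: SNPs within a region are LD-correlated,
  # so take one SNP per independent block (5 blocks x 1000 replicates)
  leads <- seq(1L, Q, by = 10L)
  ps <- 2 * pnorm(-abs(as.vector(zs[, leads])))   # 5000 draws
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("expected z follows R lambda, including the LD-confounded case", {
  Q <- 10L
  ld <- ld_matrix(0.8^abs(outer(1:Q, 1:Q, "-")),
                  sprintf("1_%d_A_G", 1:Q), regularize = FALSE)
  maf <- rep(0.3, Q)
  # no-LD case: only the query SNP has nonzero expected z
  ldI <- ld_matrix(diag(Q), sprintf("1_%d_A_G", 1:Q), regularize = FALSE)
  sc <- sim_scenario("Hc", Q, 4L, 4L, 0.2)
  set.seed(6)
  zbar <- rowMeans(vapply(1:400, function(i)
    simulate_region(sc, ldI, maf)$z, numeric(Q)))
  lam <- 0.2 * sqrt(2 * 0.3 * 0.7 * 20000 * 0.25)
  expect_equal(zbar[4L], lam, tolerance = 0.2 * lam)
  expect_lt(max(abs(zbar[-4L])), 4 / sqrt(400) * 1.5)

  # Ha with causal in LD r = 0.8 with the query: E[z_query] = 0.8 lambda
  sc2 <- sim_scenario("Ha", Q, 4L, 5L, 0.2)
  zbar2 <- rowMeans(vapply(1:400, function(i)
    simulate_region(sc2, ld, maf)$z, numeric(Q)))
  expect_equal(zbar2[4L], 0.8 * lam, tolerance = 0.15 * lam)
})

test_that("summary-level Ha confounding matches an individual-level
          logistic-regression oracle", {
  # two loci with LD r = 0.8; the causal SNP is locus 1, the query locus 2
  set.seed(7)
  f1 <- 0.3; f2 <- 0.3; r_ld <- 0.8
  D <- r_ld * sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  # haplotype frequencies (alleles coded 1/0)
  h11 <- f1 * f2 + D; h10 <- f1 - h11; h01 <- f2 - h11
  h00 <- 1 - h11 - h10 - h01
  gamma <- 0.3
  draw_study <- function(n_per_arm) {
    n_pool <- 6L * n_per_arm
    hap <- matrix(sample(1:4, 2L * n_pool, TRUE,
                         prob = c(h11, h10, h01, h00)), ncol = 2L)
    a1 <- matrix(c(1, 1, 0, 0)[hap], ncol = 2L)   # allele at locus 1
    a2 <- matrix(c(1, 0, 1, 0)[hap], ncol = 2L)
    g1 <- rowSums(a1); g2 <- rowSums(a2)
    case <- rbinom(n_pool, 1L, plogis(gamma * (g1 - mean(g1))))
    keep <- c(sample(which(case == 1L), n_per_arm),
              sample(which(case == 0L), n_per_arm))
    glm_fit <- glm(case[keep] ~ g2[keep], family = binomial())
    coef(summary(glm_fit))[2L, "z value"]
  }
  z_obs <- mean(vapply(1:150, function(i) draw_study(400L), 0))
  n <- 800L
  lam_c <- gamma * sqrt(2 * f1 * (1 - f1) * n * 0.25)
  expect_equal(z_obs, r_ld * lam_c, tolerance = 0.25 * r_ld * lam_c)
})

test_that("benchmark datasets have the requested structure and determinism", {
  counts <- c(Hn = 100, Ha = 10, Ha2 = 10, Hc = 20, Hc2 = 20)
  ds1 <- build_benchmark_dataset(counts, Q = 40L, seed = 31)
  ds2 <- build_benchmark_dataset(counts, Q = 40L, seed = 31)
  expect_identical(ds1$z, ds2$z)
  expect_identical(ds1$truth, ds2$truth)
  expect_equal(nrow(ds1$z), 160L)
  expect_equal(as.vector(table(ds1$truth$truth)[names(counts)]),
               unname(counts))
  # Hc truth has the query as causal1; Ha truth avoids it
  tt <- ds1$truth
  expect_true(all(tt$causal1[tt$truth == "Hc"] ==
                    tt$query_index[tt$truth == "Hc"]))
  expect_true(all(tt$causal1[tt$truth %in% c("Ha", "Ha2")] !=
                    tt$query_index[tt$truth %in% c("Ha", "Ha2")]))
  # two-causal pairs are distinguishable
  two <- tt[!is.na(tt$causal2)]
  R <- unclass(ds1$ld)
  expect_true(all(abs(R[cbind(two$causal1, two$causal2)]) < 0.95))
  # empty dataset
  ds0 <- build_benchmark_dataset(c(Hn = 0, Ha = 0, Ha2 = 0, Hc = 0,
                                   Hc2 = 0), Q = 10L, seed = 1)
  expect_equal(nrow(ds0$z), 0L)

  # dataset_region materializes a consistent region
  r5 <- dataset_region(ds1, 5L)
  expect_s3_class(r5, "region_summary")
  expect_equal(r5$z, ds1$z[5L, ], ignore_attr = TRUE)
  expect_equal(attr(r5, "truth"), ds1$truth$truth[5L])
})

test_that("empirical z correlation across replicates converges to R", {
  Q <- 50L
  sim <- simulate_ld(Q, ld_model(kind = "blockwise", rho = 0.9,
                                 block_size = 10L), seed = 8)
  C <- chol(unclass(sim$ld))
  set.seed(9)
  zs <- matrix(rnorm(5000 * Q), 5000) %*% C
  expect_lt(max(abs(cor(zs) - unclass(sim$ld))), 0.05)
})

test_that("simulate_rg enriches Hc covariates and is deterministic", {
  labels <- rep(c("Hn", "Ha", "Ha2", "Hc", "Hc2"), each = 200L)
  rg1 <- simulate_rg(labels, seed = 11)
  rg2 <- simulate_rg(labels, seed = 11)
  expect_identical(rg1$rg, rg2$rg)
  expect_true(all(abs(rg1$rg) <= 1))
  hc <- rg1$rg[labels %in% c("Hc", "Hc2")]
  bg <- rg1$rg[!labels %in% c("Hc", "Hc2")]
  expect_gt(mean(hc), mean(bg))
  # all-null labels: symmetric about zero within MC error
  rg0 <- simulate_rg(rep("Hn", 2000L), seed = 12)
  expect_lt(abs(mean(rg0$rg)), 3 * 0.25 / sqrt(2000))
})

test_that("dataset_abf_stats equals per-region region_stats", {
  ds <- build_benchmark_dataset(c(Hn = 20, Ha = 5, Ha2 = 5, Hc = 5,
                                  Hc2 = 5), Q = 30L, seed = 13)
  st <- dataset_abf_stats(ds)
  for (i in c(1L, 17L, 35L)) {
    region <- dataset_region(ds, i)
    ref <- region_stats(region_abf(region), region$query_index,
                        trait_id = region$trait_id,
                        x = ds$truth$rg[i])
    expect_equal(st$S[i], ref$S, tolerance = 1e-10)
    expect_equal(st$lq[i], ref$lq, tolerance = 1e-10)
  }
})

test_that("benchmark datasets round-trip through the directory format", {
  ds <- build_benchmark_dataset(c(Hn = 5, Ha = 2, Ha2 = 0, Hc = 2,
                                  Hc2 = 0), Q = 15L, seed = 14)
  dir <- withr::local_tempdir()
  write_benchmark_dataset(ds, dir)
  truth <- data.table::fread(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 9L)
  region <- read_gwas_table(file.path(dir, "t000003.tsv"))
  expect_equal(region$z, ds$z[3L, ], ignore_attr = TRUE)
  ld <- read_ld_matrix(file.path(dir, "ld.tsv"), regularize = FALSE)
  expect_equal(unclass(ld), unclass(ds$ld), tolerance = 1e-12)
})
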
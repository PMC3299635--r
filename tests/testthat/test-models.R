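# LD pruning, inbreeding f, IBS MDS and the logistic model series.

make_ds <- function(geno, spacing = 10000, phen = NULL, chr = 1L) {
  n <- nrow(geno); m <- ncol(geno)
  rownames(geno) <- sprintf("S%04d", seq_len(n))
  map <- make_map(m, spacing_bp = spacing, chroms = chr)
  genotype_dataset(geno, map,
                   phen %||% rep(c("case", "control"), length.out = n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("LD pruning drops duplicated SNPs and keeps independent ones", {
  set.seed(21)
  g <- matrix(rbinom(200 * 60, 2, 0.3), 200, 60)
  g[, 31] <- g[, 30]                      # exact duplicate, r^2 = 1
  ds <- make_ds(g)
  kept <- ld_prune(ds)
  expect_length(setdiff(ds$map$snp_id[c(30, 31)], kept), 1L)
  # independent SNPs: at least 95% retained here (sampling noise at n=200)
  expect_gte(length(kept), 0.95 * 60 - 1)
})

test_that("block-correlated panels are pruned to a few SNPs per block", {
  sim <- simulate_dataset(sim_config(n_cases = 100, n_controls = 100,
                                     n_chromosomes = 1, snps_per_chrom = 200,
                                     missing_rate = 0, ld_block_size = 10,
                                     ld_block_r = 0.95, seed = 22))
  kept <- ld_prune(sim$dataset)
  expect_lt(length(kept) / 200, 0.35)
  expect_gte(length(kept) / 200, 0.05)    # one survivor per block minimum
})

test_that("f hits the analytic extremes", {
  # all-het sample among hom-background samples at MAF ~ 0.5
  set.seed(23)
  g <- matrix(rbinom(100 * 400, 2, 0.5), 100, 400)
  g[1, ] <- 1L                            # fully heterozygous
  g[2, ] <- ifelse(g[2, ] == 1L, 0L, g[2, ])  # fully homozygous
  ds <- make_ds(g)
  fd <- inbreeding_f(ds)
  expect_lt(fd$f[1], -0.9)                # -1 up to finite-sample freq noise
  expect_equal(fd$f[2], 1)                # O = N exactly
  expect_equal(fd$n_snps_used[1], 400L)
})

test_that("f recovers simulated inbreeding and is centred under outbreeding", {
  sim <- simulate_dataset(sim_config(
    n_cases = 40, n_controls = 40, n_chromosomes = 1, snps_per_chrom = 8000,
    f_values = rep(c(0, 0.25), each = 40), missing_rate = 0.01, seed = 24))
  fd <- inbreeding_f(sim$dataset)
  expect_lt(abs(mean(fd$f[1:40])), 0.01)
  expect_lt(abs(mean(fd$f[41:80]) - 0.25), 0.015)
})

test_that("MDS gives identical coordinates to duplicated samples and separates strata", {
  set.seed(25)
  maf <- runif(800, 0.2, 0.45)
  g1 <- sapply(maf, function(p) rbinom(60, 2, p))
  g2 <- sapply(pmin(maf + 0.1, 0.95), function(p) rbinom(60, 2, p))
  g <- rbind(g1, g2)
  g[2, ] <- g[1, ]                        # duplicate of sample 1
  ds <- make_ds(g)
  mds <- mds_components(ds, k = 2)
  expect_equal(mds$C1[1], mds$C1[2], tolerance = 1e-9)
  expect_equal(mds$C2[1], mds$C2[2], tolerance = 1e-9)
  grp <- rep(c(0, 1), each = 60)
  expect_gt(abs(cor(mds$C1, grp)), 0.9)
  # components are centred
  expect_lt(abs(mean(mds$C1)), 1e-8)
  # homogeneous population: no association with arbitrary labels
  mds0 <- mds_components(make_ds(g1[, 1:400]), k = 2)
  expect_lt(abs(cor(mds0$C1, rep(c(0, 1), 30))), 0.35)
})

test_that("logistic coefficient equals the 2x2 log odds ratio", {
  # binary predictor, closed-form check
  y <- c(rep(1, 30), rep(0, 70), rep(1, 20), rep(0, 80))
  x <- rep(c(1, 0), each = 100)
  fit <- fit_logistic(y, x)
  lor <- log((30 / 70) / (20 / 80))
  expect_equal(fit$coefficient, lor, tolerance = 1e-6)
  expect_equal(fit$odds_ratio, exp(fit$coefficient))
  expect_true(fit$ci95_low <= fit$odds_ratio & fit$odds_ratio <= fit$ci95_high)
})

test_that("separation and constant predictors are flagged, not silently fit", {
  fit <- fit_logistic(c(1, 1, 0, 0), c(2, 2, -1, -1))
  expect_true(fit$separation)
  expect_error(fit_logistic(c(1, 0, 1, 0), rep(3, 4)), "constant")
})

test_that("simulated OR is recovered and the null CI has coverage", {
  set.seed(26)
  k <- rpois(3000, 0.8)
  y <- rbinom(3000, 1, plogis(-0.5 + log(2) * k))
  fit <- fit_logistic(y, k)
  expect_gt(fit$odds_ratio, 1.7)
  expect_lt(fit$odds_ratio, 2.35)
  covered <- vapply(1:100, function(r) {
    kk <- rpois(400, 0.8)
    yy <- rbinom(400, 1, 0.5)
    ff <- fit_logistic(yy, kk)
    ff$ci95_low <= 1 && 1 <= ff$ci95_high
  }, TRUE)
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 1.0)
})

test_that("the model series runs models 1-4 and adjusts for confounding", {
  set.seed(27)
  n <- 1200
  ids <- sprintf("S%04d", 1:n)
  age <- runif(n, 40, 70)
  # age inflates both disease risk and ROH count: a classic confounder
  k <- rpois(n, exp(-3 + 0.05 * age))
  y <- rbinom(n, 1, plogis(-3.5 + 0.06 * age))
  ph <- setNames(ifelse(y == 1, "case", "control"), ids)
  idx <- rep(seq_len(n), k)
  pos1 <- 1e6 + 4e6 * (seq_along(idx) %% 7)
  rohs <- make_roh(ids[idx], 1L, pos1, pos1 + 3.5e6)
  cov <- data.frame(sample_id = ids, f = rnorm(n, 0, 0.01), age = age,
                    C1 = rnorm(n, 0, 0.01), C2 = rnorm(n, 0, 0.01))
  ms <- run_model_series(rohs, ph, cov, thresholds_mb = 3)
  expect_equal(nrow(ms), 8L)              # 1 threshold x 2 predictors x 4 models
  m1 <- ms[ms$predictor == "rate" & ms$model == 1, ]
  m3 <- ms[ms$predictor == "rate" & ms$model == 3, ]
  # adjusting for age attenuates the spurious rate coefficient toward 0
  expect_lt(abs(m3$coefficient), abs(m1$coefficient))
  # model 1 is exactly the unadjusted fit
  direct <- fit_logistic(ph, as.numeric(
    roh_counts_per_sample(rohs, ids, 3)))
  expect_equal(m1$coefficient, direct$coefficient)
  expect_length(attr(ms, "mean_log10p_delta"), 3L)
})
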
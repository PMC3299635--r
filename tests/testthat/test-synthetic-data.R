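# Synthetic genotype panels: HWE behaviour, planting, determinism, effects.

test_that("background genotypes follow HWE at the configured MAF", {
  cfg <- sim_config(n_cases = 20, n_controls = 20, n_chromosomes = 1,
                    snps_per_chrom = 2000, maf_range = c(0.5, 0.5),
                    het_error_rate = 0, missing_rate = 0, seed = 11)
  sim <- simulate_dataset(cfg)
  het <- mean(sim$dataset$geno == 1L)
  expect_lt(abs(het - 0.5), 0.01)
})

test_that("F = 1 forces homozygosity; planted segments are homozygous runs", {
  cfg <- sim_config(n_cases = 2, n_controls = 2, n_chromosomes = 1,
                    snps_per_chrom = 1000, f_values = c(1, 0, 0, 0),
                    het_error_rate = 0, missing_rate = 0, seed = 2)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$dataset$geno[1, ] != 1L))

  cfg2 <- sim_config(n_cases = 3, n_controls = 3, n_chromosomes = 1,
                     snps_per_chrom = 2000,
                     planted_segments = data.frame(group = "either",
                                                   length_mb = 3,
                                                   count_per_carrier = 1,
                                                   carrier_fraction = 1),
                     het_error_rate = 0, missing_rate = 0, seed = 3)
  sim2 <- simulate_dataset(cfg2)
  tr <- sim2$truth$segments
  expect_equal(nrow(tr), 6L)
  for (r in seq_len(nrow(tr))) {
    g <- sim2$dataset$geno[tr$sample[r], tr$snp_first[r]:tr$snp_last[r]]
    expect_true(all(g %in% c(0L, 2L)))
  }
})

test_that("a fixed seed reproduces the dataset byte for byte", {
  cfg <- sim_config(n_cases = 15, n_controls = 15, snps_per_chrom = 400,
                    planted_segments = data.frame(group = "case", length_mb = 2,
                                                  count_per_carrier = 1,
                                                  carrier_fraction = 0.4),
                    seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$geno, b$dataset$geno)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth$segments, b$truth$segments)
})

test_that("genotype frequencies match HWE-with-F expectations (chi-square GOF)", {
  f <- 0.2
  cfg <- sim_config(n_cases = 5, n_controls = 5, n_chromosomes = 1,
                    snps_per_chrom = 3000, maf_range = c(0.3, 0.3),
                    f_values = f, het_error_rate = 0, missing_rate = 0,
                    seed = 13)
  sim <- simulate_dataset(cfg)
  # pool draws across samples and SNPs: 30,000 genotypes at q = 0.3
  # (orientation may flip individual SNPs at the empirical-frequency tie
  #  boundary, so count hom/het/hom regardless of which allele is which)
  q <- 0.3; p <- 1 - q
  g <- sim$dataset$geno
  n2 <- sum(g == 2L); n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  # fold the two homozygote classes: the minor-allele orientation is
  # empirical per SNP, but the het class is orientation-free
  obs <- c(hom = n0 + n2, het = n1)
  expected_het <- 2 * p * q * (1 - f)
  gof <- stats::chisq.test(obs, p = c(1 - expected_het, expected_het))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted clusters from make_common_region hit the requested carriers", {
  cfg <- sim_config(n_cases = 100, n_controls = 100, n_chromosomes = 1,
                    snps_per_chrom = 3000, missing_rate = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  lo <- sim$dataset$map$bp[1]
  spec <- data.frame(chr = 1, start_bp = lo + 6e6, end_bp = lo + 9e6,
                     carrier_fraction = 0.05, length_mb_mean = 3,
                     length_mb_sd = 0)
  cr <- make_common_region(sim$dataset, spec, seed = 6)
  expect_equal(length(unique(cr$runs$sample)), 10L)  # 5% of 200
  # sd = 0 -> all planted cluster runs identical length
  expect_equal(length(unique(cr$runs$length_kb)), 1L)
  # carrier_fraction too small for one carrier -> warning, no carriers
  tiny <- spec; tiny$carrier_fraction <- 0.001
  expect_warning(cr2 <- make_common_region(sim$dataset, tiny, seed = 7),
                 "no carriers")
  expect_equal(nrow(cr2$runs), 0L)
})

test_that("effect-model phenotype assignment saturates and nulls correctly", {
  ids <- sprintf("S%03d", 1:400)
  tr <- data.frame(sample = ids[1:100], length_mb = 9,
                   stringsAsFactors = FALSE)
  # beta large, intercept very negative: carriers are cases, others not
  lab <- assign_phenotypes(tr, ids, list(intercept = -20, beta = 40,
                                         min_length_mb = 2), seed = 8)
  expect_true(all(lab[ids[1:100]] == "case"))
  expect_true(all(lab[ids[101:400]] == "control"))
  # beta = 0: labels independent of carrier status
  set.seed(9)
  lab0 <- assign_phenotypes(tr, ids, list(intercept = 0, beta = 0), seed = 10)
  tab <- table(lab0, ids %in% tr$sample)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})
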
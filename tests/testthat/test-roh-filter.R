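# Common/rare ROH separation: carrier tracks, 1% regions, mean+3SD retention.

test_that("carrier track counts distinct individuals per SNP", {
  map <- make_map(500, spacing_bp = 10000)
  expect_equal(carrier_frequency_track(make_roh(character(0), integer(0),
                                                numeric(0), numeric(0)), map),
               integer(500))
  # one sample with two disjoint ROHs: each covered SNP counts once
  rohs <- rbind(make_roh("S1", 1L, 1e6, 3.2e6), make_roh("S1", 1L, 4e6, 6.2e6))
  tr <- carrier_frequency_track(rohs, map, 2)
  expect_true(all(tr <= 1L))
  expect_gt(sum(tr), 0)
  # matches the naive per-SNP recount on a randomized set
  set.seed(3)
  pos1 <- runif(120, 1e6, 4e9 / 1000)
  rnd <- make_roh(sprintf("S%02d", sample(30, 120, TRUE)), 1L,
                  pos1, pos1 + runif(120, 2e6, 8e6))
  # de-overlap per sample: keep first segment of any overlapping same-sample pair
  rnd <- rnd[order(rnd$sample, rnd$pos1), ]
  keep <- rep(TRUE, nrow(rnd))
  last_end <- -Inf; last_s <- ""
  for (i in seq_len(nrow(rnd))) {
    if (rnd$sample[i] == last_s && rnd$pos1[i] <= last_end) keep[i] <- FALSE
    else { last_s <- rnd$sample[i]; last_end <- rnd$pos2[i] }
  }
  rnd <- rnd[keep, ]
  expect_equal(carrier_frequency_track(rnd, map, 2),
               naive_carrier_track(rnd, map, 2))
})

test_that("regions require the 1% carrier fraction", {
  map <- make_map(300, spacing_bp = 10000)
  # 9 carriers of 1,000 over one locus: below 1%
  rohs <- make_roh(sprintf("S%02d", 1:9), 1L, rep(1e6, 9), rep(3.5e6, 9))
  tr <- carrier_frequency_track(rohs, map, 2)
  expect_equal(nrow(find_common_regions(tr, map, 1000, rohs, 2)), 0L)
  # 10 carriers reach 1%
  rohs10 <- make_roh(sprintf("S%02d", 1:10), 1L, rep(1e6, 10), rep(3.5e6, 10))
  tr10 <- carrier_frequency_track(rohs10, map, 2)
  regs <- find_common_regions(tr10, map, 1000, rohs10, 2)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$carrier_count, 10L)
  expect_gte(regs$carrier_fraction, 0.01)
})

test_that("retention cutoff follows the mean + 3 SD rule on a built cluster", {
  lens <- solve_cluster_lengths(3098.77, 3592.39 / 3)
  expect_equal(mean(lens), 3098.77, tolerance = 1e-10)
  expect_equal(pop_sd(lens) * 3, 3592.39, tolerance = 1e-10)
  map <- make_map(1200, spacing_bp = 10000)
  # all cluster runs share a common end, so every run overlaps the region
  lens_bp <- round(lens * 1000)
  rohs <- make_roh(sprintf("C%02d", seq_along(lens)), 1L,
                   12e6 - lens_bp + 1, rep(12e6, length(lens)))
  expect_equal(rohs$kb, lens, tolerance = 1e-6)
  n_samples <- 2000L  # 20 carriers = 1%
  cls <- classify_rare(rohs, map, n_samples, strata = 2)
  cutoff <- cls$regions$retention_cutoff_kb[1]
  expect_equal(cutoff, mean(rohs$kb) + 3 * pop_sd(rohs$kb))
  expect_lt(abs(cutoff - 6691.16), 0.005)
  # the 7,000 kb outlier is retained as rare; the 5,000 kb run is removed
  expect_true("C01" %in% cls$rare$sample)     # 7000 kb
  expect_false("C02" %in% cls$rare$sample)    # 5000 kb
  expect_true(all(cls$common$kb <= cutoff))
})

test_that("rare/common is a partition of the >=2 Mb input", {
  set.seed(14)
  n_samples <- 800L
  map <- make_map(1500, spacing_bp = 10000, chroms = 1:2)
  # cluster of 60 carriers (7.5%) plus scattered singles and a 9 Mb outlier
  cluster <- make_roh(sprintf("K%03d", 1:60), 1L,
                      round(runif(60, 4.8e6, 5.2e6)),
                      round(runif(60, 7.6e6, 8.2e6)))
  outlier <- make_roh("OUT1", 1L, 3e6, 12e6 - 1)   # 9 Mb through the cluster
  p1 <- round(runif(6, 1e6, 12e6))
  scattered <- make_roh(sprintf("R%03d", 1:6), 2L, p1, p1 + 2.4e6)
  short <- make_roh("SH1", 2L, 1e6, 2.2e6)         # 1.2 Mb, outside the split
  rohs <- rbind(cluster, outlier, scattered, short)
  cls <- classify_rare(rohs, map, n_samples)
  base <- rohs[rohs$kb >= 2000, ]
  got <- rbind(cls$rare, cls$common)
  expect_setequal(paste(got$sample, got$pos1), paste(base$sample, base$pos1))
  expect_equal(nrow(cls$rare) + nrow(cls$common), nrow(base))
  expect_length(intersect(paste(cls$rare$sample, cls$rare$pos1),
                          paste(cls$common$sample, cls$common$pos1)), 0)
  # the planted cluster is removed, the 9 Mb outlier retained,
  # sub-1%-frequency scattered runs retained
  expect_false(any(grepl("^K", cls$rare$sample)))
  expect_true("OUT1" %in% cls$rare$sample)
  expect_true(all(sprintf("R%03d", 1:6) %in% cls$rare$sample))
  # removing the cluster removes its region on recomputation
  cls2 <- classify_rare(rohs[!grepl("^K", rohs$sample) & rohs$sample != "OUT1", ],
                        map, n_samples)
  expect_true(is.null(cls2$regions) || nrow(cls2$regions) == 0L)
})

test_that("planted IBS cluster recovery through the genotype pipeline", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, n_chromosomes = 1,
                    snps_per_chrom = 3000,
                    common_regions = data.frame(chr = 1, start_bp = 8e6,
                                                end_bp = 10e6,
                                                carrier_fraction = 0.2,
                                                length_mb_mean = 3,
                                                length_mb_sd = 0.3),
                    seed = 15)
  sim <- simulate_dataset(cfg)
  rohs <- detect_roh(sim$dataset)
  track <- carrier_frequency_track(rohs, sim$dataset$map, 2)
  regs <- find_common_regions(track, sim$dataset$map, 300, rohs, 2)
  expect_gte(nrow(regs), 1L)
  # the widest recovered region covers the planted interval's core
  main <- regs[which.max(regs$end_bp - regs$start_bp), ]
  expect_lt(main$start_bp, 8.5e6)
  expect_gt(main$end_bp, 9.5e6)
})
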
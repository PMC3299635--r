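# Consensus pooling, complete-overlap counting and permutation correction.

test_that("pools are connected components with at least two members", {
  two <- rbind(make_roh("A", 1L, 1e6, 4e6), make_roh("B", 1L, 1e6, 4e6))
  pools <- pool_roh(two)
  expect_length(pools, 1L)
  expect_equal(nrow(pools[[1]]), 2L)
  # isolated segment: no pool
  expect_length(pool_roh(make_roh("A", 1L, 1e6, 4e6)), 0L)
  # transitive chaining A(1-5), B(4-8), C(7-12) -> one component
  abc <- rbind(make_roh("A", 1L, 1e6, 5e6), make_roh("B", 1L, 4e6, 8e6),
               make_roh("C", 1L, 7e6, 12e6))
  pools2 <- pool_roh(abc)
  expect_length(pools2, 1L)
  expect_setequal(pools2[[1]]$sample, c("A", "B", "C"))
})

test_that("pooling matches the naive pairwise transitive closure", {
  set.seed(31)
  for (rep in 1:5) {
    pos1 <- round(runif(40, 1e6, 6e7))
    rohs <- make_roh(sprintf("S%02d", 1:40), sample(1:2, 40, TRUE),
                     pos1, pos1 + round(runif(40, 2e6, 6e6)))
    pools <- pool_roh(rohs)
    # naive closure: union-find by repeated sweeps over all pairs
    key <- seq_len(nrow(rohs))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(rohs))) for (j in seq_len(nrow(rohs))) {
        if (i != j && rohs$chr[i] == rohs$chr[j] &&
            rohs$pos1[i] <= rohs$pos2[j] && rohs$pos2[i] >= rohs$pos1[j] &&
            key[i] != key[j]) {
          key[key == max(key[i], key[j])] <- min(key[i], key[j])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    naive <- Filter(function(x) length(x) >= 2, split(seq_len(nrow(rohs)), key))
    naive_sets <- lapply(naive, function(ix)
      sort(paste(rohs$sample[ix], rohs$pos1[ix])))
    got_sets <- lapply(pools, function(p) sort(paste(p$sample, p$pos1)))
    expect_setequal(got_sets, naive_sets)
  }
})

test_that("consensus is the member intersection, split when chaining empties it", {
  map <- make_map(3000, spacing_bp = 10000)
  pool <- rbind(make_roh("A", 1L, 1e6, 5e6), make_roh("B", 1L, 3e6, 8e6))
  cr <- consensus_region(pool, map)
  expect_equal(cr$start_bp, 3e6)
  expect_equal(cr$end_bp, 5e6)
  # A(1-5), B(4-8), C(7-12): A and C do not meet; two sub-group consensus
  abc <- rbind(make_roh("A", 1L, 1e6, 5e6), make_roh("B", 1L, 4e6, 8e6),
               make_roh("C", 1L, 7e6, 12e6))
  cr2 <- consensus_region(abc, map)
  expect_equal(nrow(cr2), 2L)
  expect_equal(cr2$start_bp, c(4e6, 7e6))
  expect_equal(cr2$end_bp, c(5e6, 8e6))
  # every emitted region is contained in all members of some sub-pool:
  # here {A,B} and {B,C}
  expect_true(all(cr2$n_members == 2L))
  # a consensus spanning fewer than 2 SNPs is dropped
  narrow_map <- make_map(10, spacing_bp = 5e6)
  pool3 <- rbind(make_roh("A", 1L, 1.1e6, 6e6), make_roh("B", 1L, 5.9e6, 12e6))
  expect_equal(nrow(consensus_region(pool3, narrow_map)), 0L)
  # duplicated consensus intervals across pools are de-duplicated
  four <- rbind(abc, make_roh("D", 1L, 4e6, 8e6))
  regs <- consensus_regions(four, map)
  expect_false(any(duplicated(paste(regs$chr, regs$start_bp, regs$end_bp))))
})

test_that("complete overlap requires full containment", {
  ph <- setNames(c("case", "control"), c("A", "B"))
  region <- list(chr = 1L, start_bp = 2e6, end_bp = 4e6)
  exact <- make_roh("A", 1L, 2e6, 4e6)
  expect_equal(unname(count_complete_overlap(region, exact, ph)), c(1L, 0L))
  almost <- make_roh("B", 1L, 2.02e6, 4e6)   # misses 1% at the left edge
  expect_equal(unname(count_complete_overlap(region, almost, ph)), c(0L, 0L))
})

test_that("corrected p dominates pointwise p and collapses for one region", {
  set.seed(32)
  n <- 200
  ids <- sprintf("S%03d", 1:n)
  ph <- setNames(sample(rep(c("case", "control"), each = n / 2)), ids)
  carriers <- sample(ids, 12)
  rohs <- make_roh(carriers, 1L, rep(1e6, 12), rep(4e6, 12))
  region <- data.frame(chr = 1L, start_bp = 2e6, end_bp = 3e6)
  one <- permutation_map(region, rohs, ph, n_perm = 2000, seed = 33)
  expect_equal(one$p_corrected, one$p_pointwise)
  # two regions with disjoint carrier sets
  carriers2 <- sample(setdiff(ids, carriers), 12)
  rohs2 <- rbind(rohs, make_roh(carriers2, 2L, rep(1e6, 12), rep(4e6, 12)))
  two <- permutation_map(rbind(region,
                               data.frame(chr = 2L, start_bp = 2e6,
                                          end_bp = 3e6)),
                         rohs2, ph, n_perm = 4000, seed = 34)
  expect_true(all(two$p_corrected >= two$p_pointwise - 1e-12))
  # for two near-independent identically-built null tests,
  # corrected ~ 1 - (1 - pointwise)^2
  expect_lt(abs(two$p_corrected[1] - (1 - (1 - two$p_pointwise[1])^2)), 0.06)
  expect_equal(two$carriers_cases + two$carriers_controls, c(12L, 12L))
})

test_that("gene mapping groups identical carrier sets and ranks a planted locus", {
  set.seed(35)
  n <- 300
  ids <- sprintf("S%03d", 1:n)
  ph <- setNames(rep(c("case", "control"), each = n / 2), ids)
  # planted locus: 6 cases share a 3 Mb run on chr 1 at 10-13 Mb
  planted <- make_roh(ids[1:6], 1L, rep(1e7, 6), rep(1.3e7, 6))
  # background: scattered runs in both groups on chr 2
  pos1 <- round(runif(30, 1e6, 4e7))
  bg <- make_roh(sample(ids, 30), 2L, pos1, pos1 + 2.5e6)
  rohs <- rbind(planted, bg)
  genes <- data.frame(chr = c(1L, 1L, 1L, 2L),
                      start = c(1.1e7, 1.15e7, 2e7, 5e7),
                      end = c(1.12e7, 1.17e7, 2.1e7, 5.05e7),
                      name = c("G1", "G2", "FAR", "NONE"))
  gm <- gene_mapping(genes, rohs, ph, n_perm = 2000, seed = 36)
  # G1 and G2 are spanned by exactly the same six case ROHs
  expect_equal(gm$group_id[1], gm$group_id[2])
  expect_equal(gm$p_pointwise[1], gm$p_pointwise[2])
  expect_equal(gm$carriers_cases[1:2], c(6L, 6L))
  # zero-carrier gene: p = 1
  expect_equal(gm$carriers_cases[gm$name == "NONE"], 0L)
  expect_equal(gm$p_pointwise[gm$name == "NONE"], 1)
  # the planted locus group is top-ranked
  expect_equal(sort(unique(gm$name[gm$p_pointwise == min(gm$p_pointwise)])),
               c("G1", "G2"))
})
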
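# Fixture builders and independent oracles shared across test files.

# Evenly spaced variant map on one or more chromosomes.
make_map <- function(n_snps, spacing_bp = 6500, chroms = 1L) {
  do.call(rbind, lapply(chroms, function(cc) {
    data.frame(chr = cc, snp_id = sprintf("rs%d_%d", cc, seq_len(n_snps)),
               bp = seq_len(n_snps) * spacing_bp, stringsAsFactors = FALSE)
  }))
}

# ROH data frame row(s) from coordinates; kb/nsnp/density derived the same
# way the caller derives them, nsnp defaulting to the SNP count implied by
# the map spacing when not given.
make_roh <- function(sample, chr, pos1, pos2, phenotype = NA_character_,
                     nsnp = NULL, spacing_bp = 6500) {
  if (length(sample) == 0L)
    return(data.frame(sample = character(), phenotype = character(),
                      chr = integer(), snp1 = character(), snp2 = character(),
                      pos1 = numeric(), pos2 = numeric(), kb = numeric(),
                      nsnp = integer(), density = numeric(),
                      nhet = integer(), nmiss = integer(),
                      stringsAsFactors = FALSE))
  kb <- (pos2 - pos1 + 1) / 1000
  if (is.null(nsnp)) nsnp <- pmax(2L, as.integer((pos2 - pos1) / spacing_bp) + 1L)
  data.frame(sample = sample, phenotype = phenotype, chr = chr,
             snp1 = sprintf("s%d_%.0f", chr, pos1),
             snp2 = sprintf("s%d_%.0f", chr, pos2),
             pos1 = pos1, pos2 = pos2, kb = kb, nsnp = nsnp,
             density = nsnp / kb, nhet = 0L, nmiss = 0L,
             stringsAsFactors = FALSE)
}

# Genotype sequence helpers: codes 0/2 are homozygous, 1 het, NA missing.
hom_seq <- function(n) rep(0L, n)
het_seq <- function(n) rep(1L, n)

# Random genotype sequence with given het and missing probabilities.
random_geno <- function(n, p_het, p_miss) {
  g <- ifelse(runif(n) < p_het, 1L, ifelse(runif(n) < 0.5, 0L, 2L))
  g[runif(n) < p_miss] <- NA_integer_
  g
}

# Lengths (kb) >= 2000 whose mean and population SD match the targets, with
# two prescribed outlier members included; solved in closed form by placing
# the remaining mass at two symmetric levels.
solve_cluster_lengths <- function(mean_kb, sd_kb, fixed = c(7000, 5000),
                                  n_total = 20) {
  n_free <- n_total - length(fixed)
  stopifnot(n_free %% 2 == 0)
  half <- n_free / 2
  dev_sum <- (n_total * mean_kb - sum(fixed)) - n_free * mean_kb
  dev_sq <- n_total * sd_kb^2 - sum((fixed - mean_kb)^2)
  stopifnot(dev_sq > 0)
  # half at mean+u, half at mean+v with u+v and u^2+v^2 fixed
  s <- dev_sum / half
  disc <- (dev_sq / half) / 2 - s^2 / 4
  stopifnot(disc > 0)
  u <- s / 2 + sqrt(disc)
  v <- s - u
  lens <- c(fixed, rep(mean_kb + u, half), rep(mean_kb + v, half))
  stopifnot(all(lens >= 2000))
  lens
}

# Naive per-SNP carrier recount: distinct individuals covering each SNP.
naive_carrier_track <- function(rohs, map, min_length_mb) {
  rr <- rohs[rohs$kb >= 1000 * min_length_mb, , drop = FALSE]
  vapply(seq_len(nrow(map)), function(i) {
    cov <- rr$chr == map$chr[i] & rr$pos1 <= map$bp[i] & rr$pos2 >= map$bp[i]
    length(unique(rr$sample[cov]))
  }, 0L)
}

# Two-sided Fisher p by full enumeration of hypergeometric tables with the
# observed margins (sum of table probabilities <= observed's, with the
# conventional 1e-7 relative tolerance).
enumerate_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  sum(probs[probs <= dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
}

# ROH-level null/alternative burden fixture: per-sample segment counts at a
# single length; returns a ROH data frame plus the named phenotype vector.
burden_fixture <- function(counts_case, counts_control, kb = 3500) {
  n1 <- length(counts_case); n2 <- length(counts_control)
  ids <- c(sprintf("ca%04d", seq_len(n1)), sprintf("co%04d", seq_len(n2)))
  ph <- setNames(rep(c("case", "control"), c(n1, n2)), ids)
  k <- c(counts_case, counts_control)
  idx <- rep(seq_along(k), k)
  rohs <- if (length(idx))
    make_roh(ids[idx], 1L, 1e6, 1e6 + kb * 1000 - 1,
             phenotype = unname(ph[ids[idx]]))
  else make_roh(character(0), integer(0), numeric(0), numeric(0))
  list(rohs = rohs, phenotypes = ph)
}
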
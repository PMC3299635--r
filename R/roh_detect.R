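# Sliding-window ROH calling.
#
# A window of window_snps consecutive SNPs is homozygous if it contains at
# most max_het_per_window heterozygous and max_missing_per_window missing
# genotypes. Windows never cross chromosome ends. A SNP is flagged as part of
# a ROH if the fraction of windows spanning it that are homozygous is
# strictly greater than window_hit_threshold (">5%" of windows, read
# strictly). Runs of consecutive flagged SNPs, split wherever the gap between
# adjacent SNPs exceeds max_gap_kb, become segments if they contain at least
# min_snps SNPs, span at least min_length_kb and have at least
# min_density_snp_per_kb SNPs per kb.
#
# brute_force_roh() recomputes the same contract by explicit enumeration of
# every window with no incremental shortcuts and is the testing oracle for
# call_roh_sample().

#' ROH calling parameters
#'
#' Defaults follow the standard PLINK-style window rule: 50-SNP windows with
#' at most 1 heterozygous and 1 missing call, a strict >5% spanning-window
#' threshold, a 1 Mb minimum length, 50 SNP minimum (segments of 50-10,000
#' SNPs are expected on dense chips), a density floor of 1 SNP per 50 kb and
#' a 1 Mb maximum gap between adjacent SNPs in a run.
#'
#' @param window_snps window size in SNPs
#' @param max_het_per_window,max_missing_per_window per-window caps
#' @param window_hit_threshold strict lower bound on the fraction of
#'   spanning windows that must be homozygous
#' @param min_length_kb,min_snps,min_density_snp_per_kb,max_gap_kb segment
#'   filters; density is n_snps / length_kb
#' @return list of class \code{roh_call_params}
#' @export
roh_call_params <- function(window_snps = 50L, max_het_per_window = 1L,
                            max_missing_per_window = 1L,
                            window_hit_threshold = 0.05,
                            min_length_kb = 1000, min_snps = 50L,
                            min_density_snp_per_kb = 1 / 50,
                            max_gap_kb = 1000) {
  stopifnot(window_snps >= 1, max_het_per_window >= 0,
            max_missing_per_window >= 0,
            window_hit_threshold > 0,
            min_length_kb > 0, min_snps >= 1,
            min_density_snp_per_kb > 0, max_gap_kb > 0)
  structure(list(window_snps = as.integer(window_snps),
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 window_hit_threshold = window_hit_threshold,
                 min_length_kb = min_length_kb,
                 min_snps = as.integer(min_snps),
                 min_density_snp_per_kb = min_density_snp_per_kb,
                 max_gap_kb = max_gap_kb),
            class = "roh_call_params")
}

#' Per-SNP homozygous-window hit fraction
#'
#' For each SNP, the fraction of windows of \code{window_snps} consecutive
#' SNPs containing it that satisfy the heterozygote/missing caps. Near
#' chromosome edges fewer windows span a SNP and the denominator shrinks
#' accordingly; if the chromosome is shorter than one window, no window spans
#' any SNP and the fraction is 0 everywhere.
#'
#' @param genotypes integer codes (0/1/2/NA) of one sample on one chromosome,
#'   in map order
#' @param params \code{\link{roh_call_params}}
#' @return numeric vector in [0, 1], one value per SNP
#' @export
window_hit_fraction <- function(genotypes, params = roh_call_params()) {
  n <- length(genotypes)
  w <- params$window_snps
  if (n < 1L) return(numeric(0))
  if (n < w) return(rep(0, n))
  het <- !is.na(genotypes) & genotypes == 1L
  mis <- is.na(genotypes)
  ch <- c(0, cumsum(het)); cm <- c(0, cumsum(mis))
  starts <- seq_len(n - w + 1L)
  pass <- (ch[starts + w] - ch[starts]) <= params$max_het_per_window &
          (cm[starts + w] - cm[starts]) <= params$max_missing_per_window
  s <- c(0, cumsum(pass))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n - w + 1L)
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

# Turn a logical flag vector plus positions into qualifying segments.
# Shared by the fast caller and (re-derived independently) the oracle.
.flags_to_segments <- function(flag, genotypes, bp, snp_id, params,
                               sample_id, chrom) {
  out <- list()
  n <- length(flag)
  i <- 1L
  while (i <= n) {
    if (!flag[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && flag[j + 1L] && (bp[j + 1L] - bp[j]) <= params$max_gap_kb * 1000)
      j <- j + 1L
    idx <- i:j
    kb <- (bp[j] - bp[i] + 1) / 1000
    nsnp <- length(idx)
    if (nsnp >= params$min_snps && kb >= params$min_length_kb &&
        nsnp / kb >= params$min_density_snp_per_kb) {
      gg <- genotypes[idx]
      out[[length(out) + 1L]] <- data.frame(
        sample = sample_id, phenotype = NA_character_, chr = chrom,
        snp1 = snp_id[i], snp2 = snp_id[j], pos1 = bp[i], pos2 = bp[j],
        kb = kb, nsnp = nsnp, density = nsnp / kb,
        nhet = sum(gg == 1L, na.rm = TRUE), nmiss = sum(is.na(gg)),
        stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out) else .empty_roh()
}

#' Call ROH segments for one sample on one chromosome
#'
#' @param genotypes integer codes (0/1/2/NA) in map order
#' @param map_chr data.frame with columns \code{bp} and \code{snp_id} for the
#'   same chromosome, in the same order
#' @param params \code{\link{roh_call_params}}
#' @param sample_id,chrom labels copied into the output rows
#' @return ROH data frame (possibly empty) with per-segment heterozygote and
#'   missing counts
#' @export
call_roh_sample <- function(genotypes, map_chr, params = roh_call_params(),
                            sample_id = "sample", chrom = 1L) {
  stopifnot(length(genotypes) == nrow(map_chr))
  frac <- window_hit_fraction(genotypes, params)
  flag <- frac > params$window_hit_threshold
  .flags_to_segments(flag, genotypes, map_chr$bp, map_chr$snp_id, params,
                     sample_id, chrom)
}

#' Detect ROH across a whole dataset
#'
#' Applies \code{\link{call_roh_sample}} to every sample x chromosome and
#' returns the combined segment table with phenotypes attached. Output is
#' deterministic and independent of sample or chromosome processing order.
#'
#' @param dataset a \code{\link{genotype_dataset}}
#' @param params \code{\link{roh_call_params}}
#' @param verbose print per-sample segment counts
#' @return ROH data frame; the full sample roster and phenotypes are attached
#'   as attributes \code{"samples"} and \code{"phenotypes"}
#' @export
detect_roh <- function(dataset, params = roh_call_params(), verbose = FALSE) {
  map <- dataset$map
  ids <- rownames(dataset$geno)
  chroms <- sort(unique(map$chr))
  res <- list()
  for (cc in chroms) {
    sel <- which(map$chr == cc)
    mc <- map[sel, , drop = FALSE]
    for (i in seq_along(ids)) {
      seg <- call_roh_sample(dataset$geno[i, sel], mc, params,
                             sample_id = ids[i], chrom = cc)
      if (nrow(seg)) res[[length(res) + 1L]] <- seg
    }
  }
  rohs <- if (length(res)) do.call(rbind, res) else .empty_roh()
  rohs <- rohs[order(rohs$sample, rohs$chr, rohs$pos1), , drop = FALSE]
  rownames(rohs) <- NULL
  ph <- phenotypes_of(dataset)
  rohs$phenotype <- unname(ph[rohs$sample])
  if (verbose) {
    cnt <- table(factor(rohs$sample, levels = ids))
    message(sprintf("detect_roh: %d segments in %d/%d samples",
                    nrow(rohs), sum(cnt > 0), length(ids)))
  }
  attr(rohs, "samples") <- ids
  attr(rohs, "phenotypes") <- ph
  rohs
}

#' Brute-force ROH caller (testing oracle)
#'
#' Identical output contract to \code{\link{call_roh_sample}}, computed by
#' explicit enumeration: every window's heterozygote and missing counts are
#' summed directly, every SNP's spanning windows are walked one by one, and
#' candidate runs are scanned sequentially. Intended for small inputs only.
#'
#' @inheritParams call_roh_sample
#' @return ROH data frame
#' @export
brute_force_roh <- function(genotypes, map_chr, params = roh_call_params(),
                            sample_id = "sample", chrom = 1L) {
  n <- length(genotypes)
  stopifnot(n == nrow(map_chr), n <= 5000L)
  if (n == 0L) return(.empty_roh())
  w <- params$window_snps
  flag <- logical(n)
  if (n >= w) {
    n_win <- n - w + 1L
    pass <- logical(n_win)
    for (j in seq_len(n_win)) {
      win <- genotypes[j:(j + w - 1L)]
      pass[j] <- sum(win == 1L, na.rm = TRUE) <= params$max_het_per_window &&
                 sum(is.na(win)) <= params$max_missing_per_window
    }
    for (i in seq_len(n)) {
      hits <- 0L; total <- 0L
      for (j in seq_len(n_win)) {
        if (j <= i && i <= j + w - 1L) {
          total <- total + 1L
          if (pass[j]) hits <- hits + 1L
        }
      }
      flag[i] <- hits / total > params$window_hit_threshold
    }
  }
  # sequential scan of candidate runs
  out <- .empty_roh()
  bp <- map_chr$bp
  start <- NA_integer_
  for (i in seq_len(n)) {
    if (flag[i] && is.na(start)) start <- i
    open <- !is.na(start)
    gap_break <- open && i < n && flag[i + 1L] &&
      (bp[i + 1L] - bp[i]) > params$max_gap_kb * 1000
    run_end <- open && (i == n || !flag[i + 1L] || gap_break)
    if (run_end) {
      idx <- start:i
      kb <- (bp[i] - bp[start] + 1) / 1000
      nsnp <- length(idx)
      if (nsnp >= params$min_snps && kb >= params$min_length_kb &&
          nsnp / kb >= params$min_density_snp_per_kb) {
        gg <- genotypes[idx]
        out <- rbind(out, data.frame(
          sample = sample_id, phenotype = NA_character_, chr = chrom,
          snp1 = map_chr$snp_id[start], snp2 = map_chr$snp_id[i],
          pos1 = bp[start], pos2 = bp[i], kb = kb, nsnp = nsnp,
          density = nsnp / kb, nhet = sum(gg == 1L, na.rm = TRUE),
          nmiss = sum(is.na(gg)), stringsAsFactors = FALSE))
      }
      start <- if (gap_break) i + 1L else NA_integer_
    }
  }
  out
}

#' Filter a ROH set to a minimum length
#'
#' Detection is performed once at the 1 Mb floor; sweeping the minimum length
#' (1 Mb steps up to 10 Mb in the usual design) is pure filtering.
#'
#' @param rohs ROH data frame
#' @param min_length_mb minimum segment length in Mb (kept if
#'   \code{kb >= 1000 * min_length_mb})
#' @return subset of \code{rohs}, attributes preserved
#' @export
threshold_roh <- function(rohs, min_length_mb) {
  stopifnot(min_length_mb >= 0)
  out <- rohs[rohs$kb >= 1000 * min_length_mb, , drop = FALSE]
  attr(out, "samples") <- attr(rohs, "samples")
  attr(out, "phenotypes") <- attr(rohs, "phenotypes")
  rownames(out) <- NULL
  out
}
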
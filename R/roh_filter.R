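# Separation of common (likely identical-by-state) from rare (likely
# identical-by-descent) ROHs.
#
# At each minimum-length stratum (2, 3, 4, 5 Mb by default): every region at
# which at least 1% of all individuals (cases and controls pooled) carry a
# qualifying ROH is identified from the per-SNP carrier track; a ROH
# overlapping such a region is flagged common UNLESS its length exceeds the
# region's retention cutoff, mean + 3 SD of the lengths of all qualifying
# ROHs overlapping the region. A ROH is rare iff no stratum flags it.
# Length statistics use the population SD (divide by n) for determinism on
# small clusters.

#' Per-SNP carrier-count track
#'
#' For each SNP of the map, the number of distinct individuals with at least
#' one ROH of the given minimum length covering that SNP. A sample's
#' segments on a chromosome are non-overlapping, so interval accumulation
#' counts each individual at most once per SNP.
#'
#' @param rohs ROH data frame
#' @param map variant map (chr, snp_id, bp)
#' @param min_length_mb qualifying minimum length in Mb
#' @return integer vector, one count per map row
#' @export
carrier_frequency_track <- function(rohs, map, min_length_mb = 2) {
  .check_roh(rohs)
  rr <- rohs[rohs$kb >= 1000 * min_length_mb, , drop = FALSE]
  track <- integer(nrow(map))
  if (!nrow(rr)) return(track)
  for (cc in unique(rr$chr)) {
    sel <- which(map$chr == cc)
    if (!length(sel)) next
    bp <- map$bp[sel]
    d <- numeric(length(sel) + 1L)
    rc <- rr[rr$chr == cc, , drop = FALSE]
    i1 <- findInterval(rc$pos1 - 0.5, bp) + 1L   # first SNP >= pos1
    i2 <- findInterval(rc$pos2 + 0.5, bp)        # last SNP <= pos2
    ok <- i1 <= i2 & i1 <= length(sel) & i2 >= 1L
    for (k in which(ok)) {
      d[i1[k]] <- d[i1[k]] + 1
      d[i2[k] + 1L] <- d[i2[k] + 1L] - 1
    }
    track[sel] <- as.integer(cumsum(d[seq_along(sel)]))
  }
  track
}

#' Identify common-ROH regions from a carrier track
#'
#' Maximal runs of consecutive SNPs whose carrier fraction reaches
#' \code{freq_threshold} become regions. Each region carries the mean and
#' population SD of the lengths of all qualifying ROHs overlapping it by at
#' least 1 bp, and the retention cutoff mean + \code{sd_multiplier} x SD
#' beyond which an overlapping ROH is considered a length outlier (likely a
#' true autozygous run passing through an IBS cluster) and retained.
#'
#' @param track integer carrier counts, aligned to \code{map}
#' @param map variant map
#' @param n_samples total number of individuals (cases + controls)
#' @param rohs ROH data frame the track was built from
#' @param min_length_mb qualifying minimum length of the stratum
#' @param freq_threshold carrier-fraction threshold (default 1%)
#' @param sd_multiplier retention cutoff multiplier (default 3)
#' @return data.frame of regions: chr, start_bp, end_bp, n_snps,
#'   carrier_count, carrier_fraction, overlap_length_mean_kb,
#'   overlap_length_sd_kb, retention_cutoff_kb, source_threshold_mb
#' @export
find_common_regions <- function(track, map, n_samples, rohs,
                                min_length_mb = 2, freq_threshold = 0.01,
                                sd_multiplier = 3) {
  stopifnot(length(track) == nrow(map), n_samples >= 1)
  qualifying <- rohs[rohs$kb >= 1000 * min_length_mb, , drop = FALSE]
  hot <- track / n_samples >= freq_threshold
  out <- list()
  for (cc in unique(map$chr)) {
    sel <- which(map$chr == cc)
    h <- hot[sel]
    if (!any(h)) next
    r <- rle(h)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- sel[starts[k]]; i2 <- sel[ends[k]]
      s <- map$bp[i1]; e <- map$bp[i2]
      ov <- qualifying$chr == cc & qualifying$pos1 <= e & qualifying$pos2 >= s
      lens <- qualifying$kb[ov]
      if (length(lens) < 2L) {
        message(sprintf(
          "find_common_regions: region %d:%d-%d has %d overlapping ROH(s); SD set to 0",
          cc, s, e, length(lens)))
      }
      mu <- if (length(lens)) mean(lens) else 0
      sd <- pop_sd(lens)
      carriers <- length(unique(qualifying$sample[ov]))
      out[[length(out) + 1L]] <- data.frame(
        chr = cc, start_bp = s, end_bp = e, n_snps = ends[k] - starts[k] + 1L,
        carrier_count = carriers, carrier_fraction = carriers / n_samples,
        overlap_length_mean_kb = mu, overlap_length_sd_kb = sd,
        retention_cutoff_kb = mu + sd_multiplier * sd,
        source_threshold_mb = min_length_mb, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chr = integer(), start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), carrier_count = integer(),
                      carrier_fraction = numeric(),
                      overlap_length_mean_kb = numeric(),
                      overlap_length_sd_kb = numeric(),
                      retention_cutoff_kb = numeric(),
                      source_threshold_mb = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chr, res$start_bp), , drop = FALSE]
}

#' Classify ROHs as rare or common
#'
#' Runs the regional carrier-frequency filter at each stratum in
#' \code{strata} and unions the removals: a ROH flagged common in any
#' stratum is common overall. Only ROHs of at least 2 Mb enter the
#' rare/common split (downstream analyses use the >=2 Mb set); a ROH
#' overlapping no region in any stratum is rare by default.
#'
#' @param rohs ROH data frame called at the 1 Mb floor
#' @param map variant map
#' @param n_samples total number of individuals
#' @param strata minimum-length strata in Mb (default 2:5; at 6 Mb and above
#'   no >=1% regions are expected on realistic panels)
#' @param freq_threshold,sd_multiplier see \code{\link{find_common_regions}}
#' @param overlap \code{"any"} (default): any base-pair overlap with a region
#'   makes a ROH a candidate for removal; \code{"containment"}: the ROH must
#'   lie entirely within the region
#' @return list(rare, common, regions): two disjoint ROH data frames
#'   partitioning the input >=2 Mb set, and the per-stratum region table
#' @export
classify_rare <- function(rohs, map, n_samples, strata = c(2, 3, 4, 5),
                          freq_threshold = 0.01, sd_multiplier = 3,
                          overlap = c("any", "containment")) {
  overlap <- match.arg(overlap)
  .check_roh(rohs)
  base <- rohs[rohs$kb >= 2000, , drop = FALSE]
  is_common <- rep(FALSE, nrow(base))
  all_regions <- list()
  for (t in strata) {
    track <- carrier_frequency_track(rohs, map, min_length_mb = t)
    regions <- find_common_regions(track, map, n_samples, rohs,
                                   min_length_mb = t,
                                   freq_threshold = freq_threshold,
                                   sd_multiplier = sd_multiplier)
    all_regions[[length(all_regions) + 1L]] <- regions
    if (!nrow(regions)) next
    qual <- base$kb >= 1000 * t
    for (r in seq_len(nrow(regions))) {
      rg <- regions[r, ]
      hit <- if (overlap == "any")
        qual & base$chr == rg$chr & base$pos1 <= rg$end_bp & base$pos2 >= rg$start_bp
      else
        qual & base$chr == rg$chr & base$pos1 >= rg$start_bp & base$pos2 <= rg$end_bp
      is_common <- is_common | (hit & base$kb <= rg$retention_cutoff_kb)
    }
  }
  regions <- do.call(rbind, all_regions)
  rare <- base[!is_common, , drop = FALSE]
  common <- base[is_common, , drop = FALSE]
  rownames(rare) <- rownames(common) <- NULL
  for (a in c("samples", "phenotypes")) {
    attr(rare, a) <- attr(rohs, a)
    attr(common, a) <- attr(rohs, a)
  }
  list(rare = rare, common = common, regions = regions)
}
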
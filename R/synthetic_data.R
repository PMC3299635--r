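# Synthetic genotype panels with known planted truth.
#
# Background genotypes are drawn independently per SNP from Hardy-Weinberg
# proportions inflated by a per-sample inbreeding coefficient F:
#   P(hom major) = p^2 + pqF,  P(het) = 2pq(1-F),  P(hom minor) = q^2 + pqF.
# Autozygous (IBD-like) segments are planted by overwriting genotypes with
# homozygous calls whose allele is drawn by frequency, then heterozygous
# miscalls and missingness are applied. Common IBS clusters are planted with
# make_common_region(). Everything is deterministic given the config seed.

#' Simulation configuration
#'
#' @param n_cases,n_controls sample counts per group (labels are assigned by
#'   index unless \code{effect_model} is given)
#' @param n_chromosomes,snps_per_chrom panel dimensions
#' @param mean_spacing_bp expected inter-SNP gap; the default 6,500 bp gives
#'   roughly 50 SNPs per 325 kb, so a 1 Mb run covers ~150 SNPs
#' @param maf_range minor-allele-frequency range, drawn uniformly per SNP
#' @param het_error_rate probability that a genotype inside a planted segment
#'   is miscalled heterozygous
#' @param missing_rate probability that any genotype is missing
#' @param planted_segments optional data.frame with columns
#'   \code{group} (case/control/either), \code{length_mb},
#'   \code{count_per_carrier}, \code{carrier_fraction}; optional
#'   \code{length_mb_max} (per-segment length drawn uniformly in
#'   [length_mb, length_mb_max]) and \code{chr}/\code{start_bp} (plant at a
#'   fixed locus instead of a random position)
#' @param common_regions optional data.frame passed to
#'   \code{\link{make_common_region}} (columns chr, start_bp, end_bp,
#'   carrier_fraction, length_mb_mean, length_mb_sd)
#' @param f_values per-sample inbreeding coefficient(s), recycled to the
#'   sample count
#' @param effect_model optional list(intercept, beta, min_length_mb): when
#'   set, case/control labels are drawn from a logistic model on the
#'   per-sample count of planted segments at least min_length_mb long
#' @param age_range,aao_range uniform ranges for chronological age and (cases
#'   only) age at onset, in years
#' @param cohorts labels sampled uniformly per individual
#' @param ld_block_size,ld_block_r optional block-correlation mode: within
#'   blocks of this many adjacent SNPs, each genotype copies the previous
#'   SNP's with probability \code{ld_block_r} (0 = independent SNPs)
#' @param seed integer RNG seed; a fixed config yields byte-identical output
#' @return a validated list of class \code{sim_config}
#' @export
sim_config <- function(n_cases = 200L, n_controls = 200L,
                       n_chromosomes = 2L, snps_per_chrom = 5000L,
                       mean_spacing_bp = 6500,
                       maf_range = c(0.05, 0.5),
                       het_error_rate = 0.002, missing_rate = 0.01,
                       planted_segments = NULL, common_regions = NULL,
                       f_values = 0, effect_model = NULL,
                       age_range = c(40, 70), aao_range = c(20, 50),
                       cohorts = c("DE", "FR", "UK"),
                       ld_block_size = 1L, ld_block_r = 0,
                       seed = 1L) {
  stopifnot(n_cases >= 0, n_controls >= 0, n_cases + n_controls >= 1,
            n_chromosomes >= 1, snps_per_chrom >= 2, mean_spacing_bp > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            het_error_rate >= 0, het_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            all(f_values >= -1), all(f_values <= 1),
            ld_block_size >= 1, ld_block_r >= 0, ld_block_r < 1)
  if (!is.null(planted_segments)) {
    stopifnot(all(c("group", "length_mb", "count_per_carrier",
                    "carrier_fraction") %in% names(planted_segments)),
              all(planted_segments$length_mb > 0),
              all(planted_segments$carrier_fraction >= 0),
              all(planted_segments$carrier_fraction <= 1))
  }
  if (!is.null(effect_model))
    stopifnot(is.list(effect_model), !is.null(effect_model$beta))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_chromosomes = as.integer(n_chromosomes),
                 snps_per_chrom = as.integer(snps_per_chrom),
                 mean_spacing_bp = mean_spacing_bp, maf_range = maf_range,
                 het_error_rate = het_error_rate, missing_rate = missing_rate,
                 planted_segments = planted_segments,
                 common_regions = common_regions,
                 f_values = f_values, effect_model = effect_model,
                 age_range = age_range, aao_range = aao_range,
                 cohorts = cohorts,
                 ld_block_size = as.integer(ld_block_size),
                 ld_block_r = ld_block_r,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype panel with planted truth
#'
#' @param config a \code{\link{sim_config}}
#' @return list with elements \code{dataset} (a
#'   \code{\link{genotype_dataset}}), \code{covariates} (data.frame:
#'   sample_id, phenotype, age, aao, cohort, f_true) and \code{truth}
#'   (list: \code{segments} data.frame of planted IBD runs, \code{f} named
#'   vector of true inbreeding coefficients, \code{common_runs} data.frame of
#'   planted cluster runs, \code{linear_predictor} when an effect model is set)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  ids <- sprintf("S%05d", seq_len(n))
  phenotype <- c(rep("case", config$n_cases), rep("control", config$n_controls))

  # variant map: cumulative sums of positive exponential gaps
  maps <- vector("list", config$n_chromosomes)
  for (c in seq_len(config$n_chromosomes)) {
    gaps <- pmax(1, round(stats::rexp(config$snps_per_chrom,
                                      1 / config$mean_spacing_bp)))
    maps[[c]] <- data.frame(chr = c,
                            snp_id = sprintf("rs%d_%d", c, seq_len(config$snps_per_chrom)),
                            bp = cumsum(gaps), stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  m <- nrow(map)
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  pair <- vapply(seq_len(m), function(j) sample(c("A", "C", "G", "T"), 2L), character(2))
  alleles <- data.frame(a1 = pair[1L, ], a2 = pair[2L, ], stringsAsFactors = FALSE)

  f <- rep_len(config$f_values, n)
  names(f) <- ids
  p <- 1 - maf; q <- maf
  geno <- matrix(NA_integer_, n, m, dimnames = list(ids, map$snp_id))
  for (i in seq_len(n)) {
    p2 <- q^2 + p * q * f[i]
    p1 <- 2 * p * q * (1 - f[i])
    u <- stats::runif(m)
    geno[i, ] <- ifelse(u < p2, 2L, ifelse(u < p2 + p1, 1L, 0L))
  }
  if (config$ld_block_size > 1L && config$ld_block_r > 0) {
    # block-correlation mode: copy the previous SNP's genotype with prob r
    block <- (seq_len(m) - 1L) %/% config$ld_block_size
    for (j in seq_len(m)[-1L]) {
      if (block[j] != block[j - 1L]) next
      copy <- stats::runif(n) < config$ld_block_r
      geno[copy, j] <- geno[copy, j - 1L]
    }
  }

  # planted autozygous segments
  chrom_lo <- vapply(maps, function(mm) mm$bp[1L], 0)
  chrom_hi <- vapply(maps, function(mm) mm$bp[nrow(mm)], 0)
  seg_truth <- list()
  if (!is.null(config$planted_segments)) {
    for (r in seq_len(nrow(config$planted_segments))) {
      sp <- config$planted_segments[r, ]
      pool <- switch(as.character(sp$group),
                     case = which(phenotype == "case"),
                     control = which(phenotype == "control"),
                     either = seq_len(n),
                     stop("planted segment group must be case/control/either"))
      n_carriers <- round(sp$carrier_fraction * length(pool))
      if (n_carriers < 1L) next
      carriers <- if (n_carriers == length(pool)) pool else sample(pool, n_carriers)
      fixed <- !is.null(sp$chr) && !is.na(sp$chr) &&
        !is.null(sp$start_bp) && !is.na(sp$start_bp)
      ranged <- !is.null(sp$length_mb_max) && is.finite(sp$length_mb_max) &&
        sp$length_mb_max > sp$length_mb
      for (i in carriers) {
        for (k in seq_len(sp$count_per_carrier)) {
          len_mb <- if (ranged)
            stats::runif(1, sp$length_mb, sp$length_mb_max) else sp$length_mb
          len_bp <- len_mb * 1e6
          ok_chr <- which(chrom_hi - chrom_lo + 1 >= len_bp)
          if (!length(ok_chr))
            stop(sprintf("planted segment of %.1f Mb longer than every chromosome",
                         len_mb))
          placed <- FALSE
          for (try in 1:20) {
            if (fixed) {
              cc <- sp$chr
              s <- sp$start_bp
              if (s + len_bp - 1 > chrom_hi[cc])
                stop("fixed planted segment extends beyond the chromosome")
            } else {
              cc <- if (length(ok_chr) == 1L) ok_chr else sample(ok_chr, 1L)
              s <- floor(stats::runif(1, chrom_lo[cc], chrom_hi[cc] - len_bp + 1))
            }
            e <- s + len_bp - 1
            prev <- seg_truth[vapply(seg_truth, function(z)
              z$sample == ids[i] && z$chr == cc && z$start_bp <= e && z$end_bp >= s,
              TRUE)]
            if (!length(prev) || fixed) { placed <- TRUE; break }
          }
          if (!placed) next   # sample too crowded; skip rather than overlap
          idx <- which(map$chr == cc & map$bp >= s & map$bp <= e)
          geno[i, idx] <- ifelse(stats::runif(length(idx)) < q[idx], 2L, 0L)
          seg_truth[[length(seg_truth) + 1L]] <-
            data.frame(sample = ids[i], chr = cc, start_bp = s, end_bp = e,
                       length_mb = len_mb, snp_first = min(idx),
                       snp_last = max(idx), stringsAsFactors = FALSE)
        }
      }
    }
  }
  segments <- if (length(seg_truth)) do.call(rbind, seg_truth) else
    data.frame(sample = character(), chr = integer(), start_bp = numeric(),
               end_bp = numeric(), length_mb = numeric(), snp_first = integer(),
               snp_last = integer(), stringsAsFactors = FALSE)

  # het miscalls inside planted segments, then global missingness
  if (config$het_error_rate > 0 && nrow(segments)) {
    for (r in seq_len(nrow(segments))) {
      i <- match(segments$sample[r], ids)
      idx <- segments$snp_first[r]:segments$snp_last[r]
      err <- idx[stats::runif(length(idx)) < config$het_error_rate]
      if (length(err)) geno[i, err] <- 1L
    }
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(geno)) < config$missing_rate
    geno[miss] <- NA_integer_
  }

  dataset <- genotype_dataset(geno, map, phenotype, alleles = alleles)

  common_runs <- data.frame(sample = character(), chr = integer(),
                            start_bp = numeric(), end_bp = numeric(),
                            length_kb = numeric(), stringsAsFactors = FALSE)
  if (!is.null(config$common_regions)) {
    cr <- make_common_region(dataset, config$common_regions)
    dataset <- cr$dataset
    common_runs <- cr$runs
  }
  dataset <- normalize_orientation(dataset)

  lp <- NULL
  if (!is.null(config$effect_model)) {
    ph <- assign_phenotypes(segments, ids, config$effect_model)
    dataset$phenotype <- unname(ph[ids])
    phenotype <- dataset$phenotype
    lp <- attr(ph, "linear_predictor")
  }

  age <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 1)
  aao <- ifelse(phenotype == "case",
                round(stats::runif(n, config$aao_range[1], config$aao_range[2]), 1),
                NA_real_)
  covariates <- data.frame(sample_id = ids, phenotype = phenotype, age = age,
                           aao = aao,
                           cohort = sample(config$cohorts, n, replace = TRUE),
                           f_true = unname(f), stringsAsFactors = FALSE)

  list(dataset = dataset, covariates = covariates,
       truth = list(segments = segments, f = f, common_runs = common_runs,
                    linear_predictor = lp))
}

#' Plant a common low-heterozygosity (IBS) cluster
#'
#' For each configured region, a fraction of individuals receive an
#' independent homozygous run centred inside the region with length drawn
#' Normal(length_mb_mean, length_mb_sd), truncated at 2 Mb. This produces the
#' kind of population-frequent ROH cluster that the common/rare filter must
#' flag and remove.
#'
#' @param dataset a \code{\link{genotype_dataset}}
#' @param spec data.frame with columns chr, start_bp, end_bp,
#'   carrier_fraction, length_mb_mean, length_mb_sd
#' @param seed optional seed; by default the current RNG stream is used
#' @return list(dataset = mutated dataset, runs = data.frame of planted runs)
#' @export
make_common_region <- function(dataset, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("chr", "start_bp", "end_bp", "carrier_fraction",
                  "length_mb_mean", "length_mb_sd") %in% names(spec)))
  g <- dataset$geno
  map <- dataset$map
  n <- nrow(g)
  qhat <- colSums(g == 2L, na.rm = TRUE) * 2 + colSums(g == 1L, na.rm = TRUE)
  qhat <- qhat / pmax(1, 2 * colSums(!is.na(g)))
  runs <- list()
  for (r in seq_len(nrow(spec))) {
    rr <- spec[r, ]
    on_chr <- map$bp[map$chr == rr$chr]
    if (!length(on_chr) || rr$start_bp < on_chr[1L] || rr$end_bp > on_chr[length(on_chr)])
      stop("common region outside the SNP map")
    n_carriers <- round(rr$carrier_fraction * n)
    if (n_carriers < 1L) {
      warning("carrier_fraction x n_samples < 1: no carriers planted")
      next
    }
    carriers <- sample(n, n_carriers)
    for (i in carriers) {
      len <- stats::rnorm(1, rr$length_mb_mean, rr$length_mb_sd) * 1e6
      for (try in 1:50) {
        if (len >= 2e6) break
        len <- stats::rnorm(1, rr$length_mb_mean, rr$length_mb_sd) * 1e6
      }
      len <- max(len, 2e6)
      centre <- stats::runif(1, rr$start_bp, rr$end_bp)
      s <- max(on_chr[1L], floor(centre - len / 2))
      e <- min(on_chr[length(on_chr)], floor(centre + len / 2) - 1)
      idx <- which(map$chr == rr$chr & map$bp >= s & map$bp <= e)
      g[i, idx] <- ifelse(stats::runif(length(idx)) < qhat[idx], 2L, 0L)
      runs[[length(runs) + 1L]] <-
        data.frame(sample = rownames(g)[i], chr = rr$chr, start_bp = s,
                   end_bp = e, length_kb = (e - s + 1) / 1000,
                   stringsAsFactors = FALSE)
    }
  }
  dataset$geno <- g
  list(dataset = dataset,
       runs = if (length(runs)) do.call(rbind, runs) else
         data.frame(sample = character(), chr = integer(), start_bp = numeric(),
                    end_bp = numeric(), length_kb = numeric(),
                    stringsAsFactors = FALSE))
}

#' Assign phenotypes from a logistic effect model on planted-segment counts
#'
#' Case probability is \code{plogis(intercept + beta * k)} where k is the
#' per-sample count of planted segments at least \code{min_length_mb} long.
#' With a null model (\code{effect_model = NULL}) labels are independent
#' Bernoulli(1/2) draws.
#'
#' @param truth_segments data.frame of planted segments (columns sample,
#'   length_mb), as emitted by \code{\link{simulate_dataset}}
#' @param ids character vector of all sample ids
#' @param effect_model list(intercept = 0, beta, min_length_mb = 2) or NULL
#' @param seed optional RNG seed
#' @return named character vector of case/control labels, with the linear
#'   predictor attached as attribute \code{"linear_predictor"}
#' @export
assign_phenotypes <- function(truth_segments, ids, effect_model = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  intercept <- effect_model$intercept %||% 0
  beta <- effect_model$beta %||% 0
  min_len <- effect_model$min_length_mb %||% 2
  k <- rep(0L, length(ids))
  names(k) <- ids
  if (nrow(truth_segments)) {
    long <- truth_segments[truth_segments$length_mb >= min_len, , drop = FALSE]
    if (nrow(long)) {
      tab <- table(long$sample)
      k[names(tab)] <- as.integer(tab)
    }
  }
  lp <- intercept + beta * k
  labels <- ifelse(stats::runif(length(ids)) < stats::plogis(lp),
                   "case", "control")
  names(labels) <- ids
  attr(labels, "linear_predictor") <- lp
  labels
}
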
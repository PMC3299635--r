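# Orchestration: detect -> filter -> burden -> models -> mapping, plus the
# exclusion/subgroup re-analyses and a run report. Every stage's output is
# written as TSV into a run directory together with a human-readable
# summary; a fixed seed makes the whole run byte-identical on rerun.

#' Pipeline configuration
#'
#' Inputs are either a \code{\link{sim_config}} (simulated run) or PED/MAP
#' paths plus an optional covariate TSV. All stochastic stages derive their
#' seeds from the single top-level seed.
#'
#' @param sim a \code{\link{sim_config}}, or NULL when reading files
#' @param ped_path,map_path,covariates_path input files (ignored when
#'   \code{sim} is given)
#' @param params \code{\link{roh_call_params}}
#' @param strata,freq_threshold,sd_multiplier common/rare filter settings
#' @param burden_thresholds_mb,model_thresholds_mb length sweeps
#' @param n_perm_burden,n_perm_map permutation counts
#' @param exclusion_genes_path optional interval list; samples with a
#'   >= 2 Mb ROH overlapping any listed gene are excluded and burden rerun
#' @param gene_list_path optional interval list for gene-based mapping
#' @param subgroup_cutoff_mb long-ROH subgroup cutoff (default 8)
#' @param out_dir output directory (created if absent)
#' @param seed top-level seed
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(sim = NULL, ped_path = NULL, map_path = NULL,
                            covariates_path = NULL,
                            params = roh_call_params(),
                            strata = c(2, 3, 4, 5), freq_threshold = 0.01,
                            sd_multiplier = 3,
                            burden_thresholds_mb = 2:9,
                            model_thresholds_mb = 2:9,
                            n_perm_burden = 1000L, n_perm_map = 1000L,
                            exclusion_genes_path = NULL,
                            gene_list_path = NULL,
                            subgroup_cutoff_mb = 8,
                            out_dir = tempfile("rohscan_run_"),
                            seed = 1L) {
  if (is.null(sim)) {
    for (p in c(ped_path, map_path))
      if (is.null(p) || !file.exists(p))
        stop("ped_path and map_path must exist when no sim config is given")
  }
  for (p in c(covariates_path, exclusion_genes_path, gene_list_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(list(sim = sim, ped_path = ped_path, map_path = map_path,
                 covariates_path = covariates_path, params = params,
                 strata = strata, freq_threshold = freq_threshold,
                 sd_multiplier = sd_multiplier,
                 burden_thresholds_mb = burden_thresholds_mb,
                 model_thresholds_mb = model_thresholds_mb,
                 n_perm_burden = as.integer(n_perm_burden),
                 n_perm_map = as.integer(n_perm_map),
                 exclusion_genes_path = exclusion_genes_path,
                 gene_list_path = gene_list_path,
                 subgroup_cutoff_mb = subgroup_cutoff_mb,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Exclude carriers of ROHs over listed loci
#'
#' Removes every sample having at least one ROH of the minimum length with
#' any base-pair overlap of any listed gene (the rule used when excluding
#' known recessive-disease loci before re-running burden and models), and
#' returns a per-gene audit of the removals.
#'
#' @param rohs ROH data frame
#' @param genes interval data.frame (chr, start, end, name)
#' @param samples full sample roster
#' @param min_length_mb qualifying ROH length (default 2)
#' @param overlap \code{"any"} (default) or \code{"containment"} of the gene
#'   within the ROH
#' @return list(kept, removed, audit): sample id vectors and a data.frame
#'   with one row per gene (n_removed, comma-separated sample list)
#' @export
exclude_locus_carriers <- function(rohs, genes, samples, min_length_mb = 2,
                                   overlap = c("any", "containment")) {
  overlap <- match.arg(overlap)
  if (!nrow(genes)) {
    warning("empty gene list: no samples excluded")
    return(list(kept = samples, removed = character(0),
                audit = data.frame(gene = character(), n_removed = integer(),
                                   samples = character(), stringsAsFactors = FALSE)))
  }
  qual <- rohs[rohs$kb >= 1000 * min_length_mb, , drop = FALSE]
  audit <- lapply(seq_len(nrow(genes)), function(r) {
    hit <- if (overlap == "any")
      qual$chr == genes$chr[r] & qual$pos1 <= genes$end[r] &
        qual$pos2 >= genes$start[r]
    else
      qual$chr == genes$chr[r] & qual$pos1 <= genes$start[r] &
        qual$pos2 >= genes$end[r]
    sort(unique(qual$sample[hit]))
  })
  removed <- sort(unique(unlist(audit)))
  list(kept = setdiff(samples, removed), removed = removed,
       audit = data.frame(
         gene = genes$name, n_removed = vapply(audit, length, 0L),
         samples = vapply(audit, paste, "", collapse = ","),
         stringsAsFactors = FALSE))
}

#' Long-ROH subgroup re-analyses
#'
#' Three views of the influence of individuals carrying very long
#' (> \code{cutoff_mb}) runs: (a) burden with those carrier samples
#' excluded; (b) burden with all samples but segments over the cutoff
#' dropped; (c) descriptive comparison of carriers vs non-carriers — the
#' mean rate of 2 Mb..cutoff runs, an equal-variance two-sample t-test on a
#' numeric covariate (age at onset in the motivating design), per-level
#' one-vs-rest Fisher's exact tests on a categorical covariate (cohort),
#' and a t-test on the inbreeding coefficient f when supplied.
#'
#' @param rohs ROH data frame
#' @param phenotypes named case/control vector
#' @param cutoff_mb carrier cutoff (strictly greater; default 8)
#' @param thresholds_mb burden thresholds for the re-analyses
#' @param n_perm,seed permutation settings for the burden reruns
#' @param numeric_covariate optional named numeric vector (e.g. age at onset)
#' @param categorical_covariate optional named character vector (e.g. cohort)
#' @param f optional named numeric vector of inbreeding coefficients
#' @return list(carriers, burden_excl_samples, burden_excl_segments,
#'   rate_2_to_cutoff, covariate_t, fisher_by_level, f_comparison)
#' @export
subgroup_long_roh <- function(rohs, phenotypes, cutoff_mb = 8,
                              thresholds_mb = 2:7, n_perm = 1000L, seed = 1L,
                              numeric_covariate = NULL,
                              categorical_covariate = NULL, f = NULL) {
  ph <- .check_phenotypes(phenotypes)
  samples <- names(ph)
  long <- rohs[rohs$kb > 1000 * cutoff_mb, , drop = FALSE]
  carriers <- sort(unique(long$sample))
  no_carriers <- !length(carriers)
  if (no_carriers)
    message("subgroup_long_roh: no carriers at the cutoff; carrier comparisons skipped")
  keep <- setdiff(samples, carriers)
  burden_a <- burden_table(rohs[rohs$sample %in% keep, , drop = FALSE],
                           ph[keep], thresholds_mb, n_perm, seed)
  burden_b <- burden_table(rohs[rohs$kb <= 1000 * cutoff_mb, , drop = FALSE],
                           ph, thresholds_mb, n_perm, seed + 1L)
  if (no_carriers)
    return(list(carriers = character(0), burden_excl_samples = burden_a,
                burden_excl_segments = burden_b))
  # carriers vs non-carriers: rate of 2 Mb..cutoff runs
  mid <- rohs[rohs$kb >= 2000 & rohs$kb <= 1000 * cutoff_mb, , drop = FALSE]
  kmid <- roh_counts_per_sample(mid, samples, 2)
  in_carr <- samples %in% carriers
  rate_cmp <- list(mean_carriers = mean(kmid[in_carr]),
                   mean_noncarriers = mean(kmid[!in_carr]),
                   ratio = mean(kmid[in_carr]) / mean(kmid[!in_carr]),
                   t = one_tailed_t(as.numeric(kmid[in_carr]),
                                    as.numeric(kmid[!in_carr])))
  cov_t <- NULL
  if (!is.null(numeric_covariate)) {
    a <- numeric_covariate[intersect(carriers, names(numeric_covariate))]
    b <- numeric_covariate[setdiff(names(numeric_covariate), carriers)]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) >= 2 && length(b) >= 2)
      cov_t <- stats::t.test(a, b, var.equal = TRUE)
  }
  fisher_by_level <- NULL
  if (!is.null(categorical_covariate)) {
    lv <- sort(unique(categorical_covariate))
    cc <- categorical_covariate[samples]
    fisher_by_level <- do.call(rbind, lapply(lv, function(l) {
      tab <- table(factor(in_carr, levels = c(TRUE, FALSE)),
                   factor(cc == l, levels = c(TRUE, FALSE)))
      ft <- stats::fisher.test(tab)
      data.frame(level = l,
                 carriers_in_level = tab[1L, 1L],
                 noncarriers_in_level = tab[2L, 1L],
                 odds_ratio = unname(ft$estimate), p = ft$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  f_cmp <- NULL
  if (!is.null(f)) {
    fa <- f[intersect(carriers, names(f))]
    fb <- f[setdiff(names(f), carriers)]
    fa <- fa[!is.na(fa)]; fb <- fb[!is.na(fb)]
    if (length(fa) >= 2 && length(fb) >= 2)
      f_cmp <- list(mean_carriers = mean(fa), mean_noncarriers = mean(fb),
                    t = stats::t.test(fa, fb, var.equal = TRUE))
  }
  list(carriers = carriers, burden_excl_samples = burden_a,
       burden_excl_segments = burden_b, rate_2_to_cutoff = rate_cmp,
       covariate_t = cov_t, fisher_by_level = fisher_by_level,
       f_comparison = f_cmp)
}

.write_tsv <- function(x, dir, name) {
  p <- file.path(dir, name)
  utils::write.table(format(x, digits = 15, scientific = FALSE, trim = TRUE),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

#' Run the full analysis pipeline
#'
#' Simulates or reads genotypes, detects ROH, separates common from rare,
#' computes the burden table, the covariates (LD pruning, f, MDS) and the
#' logistic model series, maps consensus regions (and genes when a list is
#' supplied), applies the optional locus-exclusion rerun and the long-ROH
#' subgroup analyses, and writes every stage's table plus a summary into
#' the configured run directory.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param verbose log stage progress via \code{message()}
#' @return invisibly, a list with every stage's in-memory result
#' @export
run_full_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (verbose) message(sprintf(...))
  covariates_in <- NULL
  if (!is.null(config$sim)) {
    log("stage simulate: seed %d", config$sim$seed)
    sim <- simulate_dataset(config$sim)
    dataset <- sim$dataset
    covariates_in <- sim$covariates
  } else {
    log("stage read: %s", config$ped_path)
    dataset <- read_plink_text(config$ped_path, config$map_path)
    if (!is.null(config$covariates_path))
      covariates_in <- read_covariates(config$covariates_path)
    sim <- NULL
  }
  ph <- phenotypes_of(dataset)
  n_samples <- length(ph)

  log("stage detect: %d samples x %d SNPs", n_samples, ncol(dataset$geno))
  rohs <- detect_roh(dataset, config$params)
  write_roh_table(rohs, file.path(config$out_dir, "roh_all.tsv"))

  log("stage filter: strata %s", paste(config$strata, collapse = ","))
  cls <- classify_rare(rohs, dataset$map, n_samples, config$strata,
                       config$freq_threshold, config$sd_multiplier)
  write_roh_table(cls$rare, file.path(config$out_dir, "roh_rare.tsv"))
  write_roh_table(cls$common, file.path(config$out_dir, "roh_common.tsv"))
  if (!is.null(cls$regions) && nrow(cls$regions))
    .write_tsv(cls$regions, config$out_dir, "common_regions.tsv")

  log("stage burden: B = %d", config$n_perm_burden)
  burden <- burden_table(cls$rare, ph, config$burden_thresholds_mb,
                         config$n_perm_burden, seed = config$seed + 101L)
  .write_tsv(burden, config$out_dir, "burden.tsv")

  log("stage models")
  pruned <- ld_prune(dataset)
  fdf <- inbreeding_f(dataset, pruned)
  mds <- mds_components(dataset, k = 2, snp_subset = pruned)
  cov <- data.frame(sample_id = names(ph), stringsAsFactors = FALSE)
  cov$f <- fdf$f[match(cov$sample_id, fdf$sample_id)]
  cov$age <- if (!is.null(covariates_in) && "age" %in% names(covariates_in))
    covariates_in$age[match(cov$sample_id, covariates_in$sample_id)] else NA_real_
  cov$C1 <- mds$C1[match(cov$sample_id, mds$sample_id)]
  cov$C2 <- mds$C2[match(cov$sample_id, mds$sample_id)]
  models <- run_model_series(cls$rare, ph, cov, config$model_thresholds_mb)
  .write_tsv(models, config$out_dir, "models.tsv")
  write_covariates(cov, file.path(config$out_dir, "covariates.tsv"))

  log("stage mapping: B = %d", config$n_perm_map)
  regs <- consensus_regions(cls$rare, dataset$map)
  mapping <- NULL
  if (nrow(regs)) {
    mapping <- permutation_map(regs, cls$rare, ph, config$n_perm_map,
                               seed = config$seed + 202L)
    mapping <- mapping[order(mapping$p_pointwise,
                             -mapping$carriers_cases), , drop = FALSE]
    .write_tsv(mapping, config$out_dir, "consensus_mapping.tsv")
  }
  genes_res <- NULL
  if (!is.null(config$gene_list_path)) {
    genes <- read_intervals(config$gene_list_path)
    if (nrow(genes)) {
      genes_res <- gene_mapping(genes, cls$rare, ph, config$n_perm_map,
                                seed = config$seed + 303L)
      .write_tsv(genes_res, config$out_dir, "gene_mapping.tsv")
    }
  }

  exclusion <- NULL
  if (!is.null(config$exclusion_genes_path)) {
    excl_genes <- read_intervals(config$exclusion_genes_path)
    exclusion <- exclude_locus_carriers(rohs, excl_genes, names(ph))
    .write_tsv(exclusion$audit, config$out_dir, "exclusion_audit.tsv")
    if (length(exclusion$kept) &&
        length(unique(ph[exclusion$kept])) == 2L) {
      burden_excl <- burden_table(
        cls$rare[cls$rare$sample %in% exclusion$kept, , drop = FALSE],
        ph[exclusion$kept], config$burden_thresholds_mb,
        config$n_perm_burden, seed = config$seed + 404L)
      .write_tsv(burden_excl, config$out_dir, "burden_after_exclusion.tsv")
      exclusion$burden <- burden_excl
    }
  }

  log("stage subgroup: cutoff %g Mb", config$subgroup_cutoff_mb)
  subgroup <- subgroup_long_roh(
    cls$rare, ph, config$subgroup_cutoff_mb,
    thresholds_mb = config$burden_thresholds_mb[
      config$burden_thresholds_mb < config$subgroup_cutoff_mb],
    n_perm = config$n_perm_burden, seed = config$seed + 505L,
    numeric_covariate = if (!is.null(covariates_in) && "aao" %in% names(covariates_in))
      stats::setNames(covariates_in$aao, covariates_in$sample_id) else NULL,
    categorical_covariate = if (!is.null(covariates_in) && "cohort" %in% names(covariates_in))
      stats::setNames(covariates_in$cohort, covariates_in$sample_id) else NULL,
    f = stats::setNames(cov$f, cov$sample_id))

  summary_path <- file.path(config$out_dir, "summary.txt")
  con <- file(summary_path, "wt")
  writeLines(c(
    sprintf("rohscan run (seed %d)", config$seed),
    sprintf("samples: %d (%d cases, %d controls); SNPs: %d",
            n_samples, sum(ph == "case", na.rm = TRUE),
            sum(ph == "control", na.rm = TRUE), ncol(dataset$geno)),
    sprintf("ROH segments: %d total, %d rare (>=2 Mb), %d common",
            nrow(rohs), nrow(cls$rare), nrow(cls$common)),
    "", "Burden (rare ROH):",
    utils::capture.output(print(
      within(burden, {
        proportion_cases <- sprintf("%.2f%%", 100 * proportion_cases)
        proportion_controls <- sprintf("%.2f%%", 100 * proportion_controls)
        ratio_proportion <- sprintf("%.2f", ratio_proportion)
        ratio_rate <- sprintf("%.2f", ratio_rate)
        p_proportion <- signif(p_proportion, 2)
        p_rate <- signif(p_rate, 2)
      }), row.names = FALSE)),
    "", "Top mapped consensus regions:",
    if (!is.null(mapping))
      utils::capture.output(print(utils::head(mapping, 10), row.names = FALSE))
    else "  (none)"), con)
  close(con)

  invisible(list(dataset = dataset, sim = sim, rohs = rohs, classified = cls,
                 burden = burden, covariates = cov, models = models,
                 mapping = mapping, genes = genes_res, exclusion = exclusion,
                 subgroup = subgroup, out_dir = config$out_dir))
}
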
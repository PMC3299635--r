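# Covariate machinery and logistic model series.
#
# The inbreeding coefficient f is the method-of-moments excess-homozygosity
# statistic f = (O_hom - E_hom) / (N - E_hom) computed per sample on an
# LD-pruned SNP subset, with the small-sample allele-frequency correction
# 2*p*q * A/(A-1) (A = non-missing allele count at the SNP), so that the
# expected heterozygosity term is unbiased. Ancestry covariates C1/C2 come
# from classical metric scaling of the genome-wide 1 - IBS distance matrix.
# Models 1-4 relate a per-threshold ROH predictor (carrier indicator or
# count) to case status with cumulative covariate sets
# {}, {f}, {f, age}, {f, age, C1, C2}.

#' Greedy windowed LD pruning
#'
#' Slides a window of \code{window_snps} SNPs along each chromosome in steps
#' of \code{step_snps}; within a window, while any pair of retained SNPs has
#' squared genotype correlation above \code{r2_max}, the member of the worst
#' pair with the lower minor-allele frequency is dropped (ties: the later
#' map position).
#'
#' @param dataset a \code{\link{genotype_dataset}}
#' @param window_snps,step_snps,r2_max pruning parameters (defaults 50/5/0.2)
#' @return character vector of retained SNP ids
#' @export
ld_prune <- function(dataset, window_snps = 50L, step_snps = 5L, r2_max = 0.2) {
  g <- dataset$geno
  map <- dataset$map
  maf <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(maf, 1 - maf)
  removed <- rep(FALSE, ncol(g))
  for (cc in unique(map$chr)) {
    sel <- which(map$chr == cc)
    nidx <- length(sel)
    start <- 1L
    repeat {
      win <- sel[start:min(start + window_snps - 1L, nidx)]
      active <- win[!removed[win]]
      if (length(active) > 1L) {
        repeat {
          r2 <- suppressWarnings(
            stats::cor(g[, active, drop = FALSE],
                       use = "pairwise.complete.obs"))^2
          diag(r2) <- 0
          r2[is.na(r2)] <- 0
          mx <- max(r2)
          if (mx <= r2_max) break
          w <- which(r2 == mx, arr.ind = TRUE)[1L, ]
          a <- active[w[1L]]; b <- active[w[2L]]
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else max(a, b)               # tie: later map position
          removed[drop] <- TRUE
          active <- active[active != drop]
          if (length(active) < 2L) break
        }
      }
      if (start + window_snps - 1L >= nidx) break
      start <- start + step_snps
    }
  }
  colnames(g)[!removed]
}

#' Method-of-moments inbreeding coefficient per sample
#'
#' @param dataset a \code{\link{genotype_dataset}}
#' @param snp_subset optional character vector of SNP ids (typically the
#'   LD-pruned subset); default all SNPs
#' @return data.frame(sample_id, f, n_snps_used); f is NA (flagged) for a
#'   degenerate panel where N = E_hom
#' @export
inbreeding_f <- function(dataset, snp_subset = NULL) {
  g <- dataset$geno
  if (!is.null(snp_subset)) {
    miss <- setdiff(snp_subset, colnames(g))
    if (length(miss)) stop("snp_subset contains unknown SNP ids")
    g <- g[, snp_subset, drop = FALSE]
  }
  nonmiss <- !is.na(g)
  n_geno <- colSums(nonmiss)
  q <- colSums(g, na.rm = TRUE) / pmax(1, 2 * n_geno)
  A <- 2 * n_geno                                   # non-missing allele count
  e_het <- ifelse(A > 1, 2 * q * (1 - q) * A / (A - 1), 0)
  e_hom_snp <- 1 - e_het
  O <- rowSums(g != 1L, na.rm = TRUE)               # observed homozygous
  N <- rowSums(nonmiss)
  E <- as.vector(nonmiss %*% e_hom_snp)
  denom <- N - E
  f <- ifelse(abs(denom) < 1e-12, NA_real_, (O - E) / denom)
  if (anyNA(f))
    warning(sprintf("%d sample(s) with degenerate panel (N = E_hom); f set to NA",
                    sum(is.na(f))))
  data.frame(sample_id = rownames(g), f = f, n_snps_used = N,
             stringsAsFactors = FALSE)
}

#' Classical MDS of the genome-wide IBS distance matrix
#'
#' Pairwise distance is 1 - IBS similarity, where IBS similarity is the mean
#' over SNPs non-missing in both samples of (shared alleles)/2. Components
#' come from classical metric scaling (double-centred Gram matrix,
#' eigenvectors scaled by the square root of their eigenvalues), are centred
#' at zero and ordered by decreasing eigenvalue. Signs are fixed by making
#' each component's largest-magnitude loading positive, so results are
#' reproducible across runs.
#'
#' @param dataset a \code{\link{genotype_dataset}}
#' @param k number of components (default 2)
#' @param snp_subset optional character vector of SNP ids
#' @return data.frame(sample_id, C1, ..., Ck)
#' @export
mds_components <- function(dataset, k = 2L, snp_subset = NULL) {
  g <- dataset$geno
  if (!is.null(snp_subset)) g <- g[, snp_subset, drop = FALSE]
  n <- nrow(g)
  stopifnot(n >= k + 1)
  M <- !is.na(g)
  shared <- M %*% t(M)
  if (any(shared == 0))
    stop("a sample pair shares no non-missing SNPs; filter missingness first")
  # sum over shared SNPs of |g_i - g_j| via code-indicator cross-products
  H <- lapply(0:2, function(v) {
    x <- matrix(0, n, ncol(g)); x[M & g == v] <- 1; x
  })
  C01 <- H[[1]] %*% t(H[[2]]); C12 <- H[[2]] %*% t(H[[3]])
  C02 <- H[[1]] %*% t(H[[3]])
  absdiff <- (C01 + t(C01) + C12 + t(C12)) + 2 * (C02 + t(C02))
  D <- absdiff / (2 * shared)                       # 1 - mean(shared alleles)/2
  diag(D) <- 0
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  pts <- fit$points
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  out <- data.frame(sample_id = rownames(g), pts, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", paste0("C", seq_len(ncol(pts))))
  rownames(out) <- NULL
  out
}

#' Logistic regression of case status on a ROH predictor
#'
#' Maximum-likelihood fit (IRLS, gradient tolerance 1e-8, at most 100
#' iterations) of \code{case ~ predictor + covariates} on complete cases.
#' Non-convergence and quasi-separation are flagged, never silently dropped.
#'
#' @param phenotype case/control vector (character, factor or 0/1)
#' @param predictor numeric per-sample predictor (indicator or count)
#' @param covariates optional data.frame of numeric covariates, aligned with
#'   \code{phenotype}
#' @return list of class \code{roh_logit}: coefficient, se, odds_ratio,
#'   ci95_low, ci95_high, p_wald, n_used, n_dropped, converged, separation
#' @export
fit_logistic <- function(phenotype, predictor, covariates = NULL) {
  y <- if (is.numeric(phenotype)) phenotype else
    ifelse(as.character(phenotype) == "case", 1,
           ifelse(as.character(phenotype) == "control", 0, NA))
  df <- data.frame(y = y, predictor = predictor)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (stats::var(df$predictor) == 0) stop("constant predictor after complete-case filtering")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  # quasi-separation can converge without a warning on tiny n; the fitted
  # probabilities pinned to 0/1 give it away
  if (any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
    separation <- TRUE
  sm <- summary(fit)$coefficients
  co <- sm["predictor", ]
  structure(list(coefficient = unname(co[1L]), se = unname(co[2L]),
                 odds_ratio = exp(unname(co[1L])),
                 ci95_low = exp(unname(co[1L]) - 1.96 * unname(co[2L])),
                 ci95_high = exp(unname(co[1L]) + 1.96 * unname(co[2L])),
                 p_wald = unname(co[4L]),
                 n_used = nrow(df), n_dropped = sum(!cc),
                 converged = fit$converged, separation = separation),
            class = "roh_logit")
}

#' @export
print.roh_logit <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d%s%s\n",
              x$odds_ratio, x$ci95_low, x$ci95_high, x$p_wald, x$n_used,
              if (!x$converged) " [not converged]" else "",
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Run the four-model logistic series
#'
#' For each length threshold and each predictor encoding — the carrier
#' indicator ("proportion") and the per-sample count ("rate") — fits Model 1
#' (unadjusted), Model 2 (f), Model 3 (f, age) and Model 4 (f, age, C1, C2),
#' complete cases per model.
#'
#' @param rohs ROH data frame (typically the rare set)
#' @param phenotypes named case/control vector
#' @param covariates data.frame with columns sample_id, f, age, C1, C2
#' @param thresholds_mb length thresholds in Mb
#' @return data.frame of results (one row per threshold x predictor x
#'   model); the mean -log10(p) change between consecutive models is
#'   attached as attribute \code{"mean_log10p_delta"}
#' @export
run_model_series <- function(rohs, phenotypes, covariates,
                             thresholds_mb = 2:9) {
  ph <- .check_phenotypes(phenotypes)
  ph <- ph[!is.na(ph)]
  samples <- names(ph)
  need <- c("sample_id", "f", "age", "C1", "C2")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("covariates lack column(s): ", paste(miss, collapse = ", "))
  cov <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
  model_sets <- list(character(0), "f", c("f", "age"), c("f", "age", "C1", "C2"))
  rows <- list()
  for (t in thresholds_mb) {
    x <- as.numeric(roh_counts_per_sample(rohs, samples, t))
    preds <- list(proportion = as.numeric(x > 0), rate = x)
    for (pn in names(preds)) {
      for (mi in seq_along(model_sets)) {
        cset <- model_sets[[mi]]
        fit <- tryCatch(
          fit_logistic(ph, preds[[pn]],
                       if (length(cset)) cov[, cset, drop = FALSE] else NULL),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          threshold_mb = t, predictor = pn, model = mi,
          coefficient = if (is.null(fit)) NA_real_ else fit$coefficient,
          odds_ratio = if (is.null(fit)) NA_real_ else fit$odds_ratio,
          ci95_low = if (is.null(fit)) NA_real_ else fit$ci95_low,
          ci95_high = if (is.null(fit)) NA_real_ else fit$ci95_high,
          p_wald = if (is.null(fit)) NA_real_ else fit$p_wald,
          n_used = if (is.null(fit)) NA_integer_ else fit$n_used,
          converged = if (is.null(fit)) NA else fit$converged,
          separation = if (is.null(fit)) NA else fit$separation,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  deltas <- vapply(2:4, function(mi) {
    a <- out$p_wald[out$model == mi]
    b <- out$p_wald[out$model == mi - 1L]
    mean(-log10(a) + log10(b), na.rm = TRUE)
  }, 0)
  names(deltas) <- c("model2_vs_1", "model3_vs_2", "model4_vs_3")
  attr(out, "mean_log10p_delta") <- deltas
  out
}
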
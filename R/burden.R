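# Case-control homozygosity burden.
#
# For each minimum-length threshold: the proportion of individuals with at
# least one qualifying ROH, and the mean number of qualifying ROHs per
# individual (rate), per group. Group means are compared with one-tailed
# equal-variance t statistics (cases > controls) and with empirical p-values
# from case/control label permutation using the add-one estimator
# p = (1 + #{permuted >= observed}) / (1 + n_perm).

#' Permutation p-value for a label statistic
#'
#' Permutes the label vector uniformly (preserving group sizes) and returns
#' the add-one tail estimate, which lies in (0, 1] and never returns zero.
#'
#' @param statistic_fn function(labels) -> scalar; must be exchangeable
#'   under the null
#' @param labels label vector passed to \code{statistic_fn}
#' @param n_perm number of permutations (>= 1)
#' @param seed optional RNG seed for determinism
#' @param alternative only \code{"greater"} (upper tail) is defined
#' @return p-value in (0, 1]
#' @export
permutation_pvalue <- function(statistic_fn, labels, n_perm = 10000L,
                               seed = NULL, alternative = "greater") {
  stopifnot(n_perm >= 1, identical(alternative, "greater"))
  if (!is.null(seed)) set.seed(seed)
  obs <- statistic_fn(labels)
  n <- length(labels)
  tol <- .perm_tol(obs)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (statistic_fn(labels[sample.int(n)]) >= obs - tol) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

# Fast path used internally: permutation p for a difference in group means
# of a numeric per-sample vector, cases > controls.
.perm_p_mean_diff <- function(x, is_case, n_perm) {
  n <- length(x); n1 <- sum(is_case)
  obs <- mean(x[is_case]) - mean(x[!is_case])
  tol <- .perm_tol(obs)
  tot <- sum(x)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    s1 <- sum(x[sample.int(n, n1)])
    if (s1 / n1 - (tot - s1) / (n - n1) >= obs - tol) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' One-tailed two-sample t-test (cases > controls)
#'
#' Equal-variance (pooled) form by default, matching the convention of
#' simple burden comparisons; Welch's unequal-variance form by flag. With
#' zero pooled variance the statistic is undefined and a degenerate result
#' is returned: p = 1 when the means are equal, 0 or 1 by the sign of the
#' mean difference otherwise.
#'
#' @param values_cases,values_controls numeric vectors, each of length >= 2
#' @param var_equal pooled-variance form (default TRUE)
#' @return list(t, df, p, degenerate)
#' @export
one_tailed_t <- function(values_cases, values_controls, var_equal = TRUE) {
  n1 <- length(values_cases); n2 <- length(values_controls)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- mean(values_cases); m2 <- mean(values_controls)
  v1 <- stats::var(values_cases); v2 <- stats::var(values_controls)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (!is.finite(se) || se == 0) {
    p <- if (m1 == m2) 1 else if (m1 > m2) 0 else 1
    return(list(t = NA_real_, df = NA_real_, p = p, degenerate = TRUE))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = stats::pt(t, df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Per-sample qualifying-ROH counts
#'
#' @param rohs ROH data frame
#' @param samples character vector: the full roster (samples with zero
#'   segments must be counted)
#' @param min_length_mb qualifying minimum length in Mb
#' @return integer vector named by sample
#' @export
roh_counts_per_sample <- function(rohs, samples, min_length_mb) {
  k <- stats::setNames(rep(0L, length(samples)), samples)
  rr <- rohs[rohs$kb >= 1000 * min_length_mb, , drop = FALSE]
  if (nrow(rr)) {
    tab <- table(factor(rr$sample, levels = samples))
    k[] <- as.integer(tab)
  }
  k
}

#' Case-control burden table across length thresholds
#'
#' @param rohs ROH data frame (typically the rare set)
#' @param phenotypes named case/control vector for every analysed sample
#' @param thresholds_mb minimum-length thresholds in Mb
#' @param n_perm permutations per empirical p-value
#' @param seed RNG seed (one stream drives all thresholds, so results are
#'   reproducible as a whole)
#' @return data.frame with one row per threshold: group proportions and
#'   rates, case/control ratios, one-tailed t p-values and permutation
#'   empirical p-values for both measures
#' @export
burden_table <- function(rohs, phenotypes, thresholds_mb = 1:10,
                         n_perm = 10000L, seed = 1L) {
  ph <- .check_phenotypes(phenotypes)
  ph <- ph[!is.na(ph)]
  samples <- names(ph)
  is_case <- ph == "case"
  if (!sum(is_case) || !sum(!is_case))
    stop("both a case and a control group are required")
  set.seed(seed)
  rows <- lapply(thresholds_mb, function(t) {
    x <- as.numeric(roh_counts_per_sample(rohs, samples, t))
    ind <- as.numeric(x > 0)
    prop_ca <- mean(ind[is_case]); prop_co <- mean(ind[!is_case])
    rate_ca <- mean(x[is_case]); rate_co <- mean(x[!is_case])
    t_prop <- one_tailed_t(ind[is_case], ind[!is_case])
    t_rate <- one_tailed_t(x[is_case], x[!is_case])
    data.frame(
      threshold_mb = t,
      proportion_cases = prop_ca, proportion_controls = prop_co,
      rate_cases = rate_ca, rate_controls = rate_co,
      ratio_proportion = prop_ca / prop_co, ratio_rate = rate_ca / rate_co,
      p_t_proportion = t_prop$p, p_t_rate = t_rate$p,
      p_proportion = .perm_p_mean_diff(ind, is_case, n_perm),
      p_rate = .perm_p_mean_diff(x, is_case, n_perm),
      n_perm = n_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
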
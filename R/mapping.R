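# Locus-level homozygosity mapping.
#
# Rare ROHs are pooled into connected components of the pairwise-overlap
# graph per chromosome (>= 2 members). Each pool's consensus region is the
# intersection of its member intervals; when transitive chaining makes the
# full intersection empty, the pool is split into its maximal sub-groups
# with a nonempty common intersection (for 1-D intervals these are exactly
# the maximal cliques of the overlap graph, by the Helly property). Only
# consensus intervals containing at least 2 SNPs of the map are kept, and
# identical intervals arising from different pools are de-duplicated.
#
# An individual carries a region iff at least one of their ROHs contains the
# whole region ("complete overlap"). The permutation statistic per region is
# its case-carrier count, equivalent to case excess at fixed group sizes;
# pointwise p-values use the add-one estimator and family-wise correction is
# max-T over per-region standardised statistics (Bonferroni also reported).

#' Pool overlapping ROHs
#'
#' Connected components of the pairwise-overlap graph per chromosome,
#' restricted to components with at least 2 segments, ordered by leftmost
#' coordinate.
#'
#' @param rohs ROH data frame (the rare >= 2 Mb set in the standard design)
#' @return list of data.frames, one per pool, each carrying its member rows
#'   of \code{rohs}
#' @export
pool_roh <- function(rohs) {
  .check_roh(rohs)
  pools <- list()
  for (cc in sort(unique(rohs$chr))) {
    rc <- rohs[rohs$chr == cc, , drop = FALSE]
    rc <- rc[order(rc$pos1, rc$pos2), , drop = FALSE]
    if (!nrow(rc)) next
    comp_start <- 1L
    max_end <- rc$pos2[1L]
    flush <- function(from, to) {
      if (to - from >= 1L)               # >= 2 members
        pools[[length(pools) + 1L]] <<- rc[from:to, , drop = FALSE]
    }
    if (nrow(rc) > 1L) for (i in 2L:nrow(rc)) {
      if (rc$pos1[i] > max_end) {        # no base-pair overlap with component
        flush(comp_start, i - 1L)
        comp_start <- i
        max_end <- rc$pos2[i]
      } else max_end <- max(max_end, rc$pos2[i])
    }
    flush(comp_start, nrow(rc))
  }
  pools
}

# Maximal sub-groups (>= 2 members) of a set of intervals on one chromosome
# that share a common point: the maximal cliques of the 1-D overlap graph.
# Every maximal clique has a common point that is some member's start, so
# candidate groups are "all intervals covering start_j"; subsets are pruned.
.maximal_overlap_groups <- function(start, end) {
  cand <- lapply(seq_along(start), function(j)
    which(start <= start[j] & end >= start[j]))
  cand <- unique(cand[vapply(cand, length, 0L) >= 2L])
  if (length(cand) < 2L) return(cand)
  keep <- rep(TRUE, length(cand))
  for (a in seq_along(cand)) for (b in seq_along(cand)) {
    if (a != b && keep[a] && all(cand[[a]] %in% cand[[b]]) &&
        length(cand[[a]]) < length(cand[[b]])) keep[a] <- FALSE
  }
  cand[keep]
}

#' Consensus region(s) of one ROH pool
#'
#' @param pool data.frame of member segments (one chromosome)
#' @param map variant map
#' @return data.frame of consensus intervals (chr, start_bp, end_bp, n_snps,
#'   n_members), possibly empty after the >= 2 SNP rule
#' @export
consensus_region <- function(pool, map) {
  stopifnot(nrow(pool) >= 2L, length(unique(pool$chr)) == 1L)
  cc <- pool$chr[1L]
  bp <- map$bp[map$chr == cc]
  groups <- .maximal_overlap_groups(pool$pos1, pool$pos2)
  out <- list()
  for (gset in groups) {
    s <- max(pool$pos1[gset]); e <- min(pool$pos2[gset])
    if (s > e) next
    n_in <- sum(bp >= s & bp <= e)
    if (n_in >= 2L)
      out[[length(out) + 1L]] <- data.frame(
        chr = cc, start_bp = s, end_bp = e, n_snps = n_in,
        n_members = length(gset), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chr = integer(), start_bp = numeric(), end_bp = numeric(),
               n_snps = integer(), n_members = integer(), stringsAsFactors = FALSE)
}

#' All consensus regions of a ROH set
#'
#' Pools the segments, extracts every consensus interval and de-duplicates
#' identical (chr, start, end) triples across pools.
#'
#' @param rohs ROH data frame
#' @param map variant map
#' @return data.frame of unique consensus regions ordered by position
#' @export
consensus_regions <- function(rohs, map) {
  pools <- pool_roh(rohs)
  regs <- if (length(pools))
    do.call(rbind, lapply(pools, consensus_region, map = map)) else NULL
  if (is.null(regs) || !nrow(regs))
    return(data.frame(chr = integer(), start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), n_members = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(regs$chr, regs$start_bp, regs$end_bp)
  regs <- regs[!duplicated(key), , drop = FALSE]
  regs <- regs[order(regs$chr, regs$start_bp, regs$end_bp), , drop = FALSE]
  rownames(regs) <- NULL
  regs
}

#' Count complete-overlap carriers of a region
#'
#' An individual is a carrier iff at least one of their ROHs contains the
#' whole region; each individual counts once.
#'
#' @param region list or one-row data.frame with chr, start_bp, end_bp
#' @param rohs ROH data frame
#' @param phenotypes named case/control vector
#' @return integer vector c(carriers_cases, carriers_controls)
#' @export
count_complete_overlap <- function(region, rohs, phenotypes) {
  ph <- .check_phenotypes(phenotypes)
  hit <- rohs$chr == region$chr & rohs$pos1 <= region$start_bp &
    rohs$pos2 >= region$end_bp
  carriers <- unique(rohs$sample[hit])
  c(carriers_cases = sum(ph[carriers] == "case", na.rm = TRUE),
    carriers_controls = sum(ph[carriers] == "control", na.rm = TRUE))
}

# Carrier index sets (positions into `samples`) per region, by full
# containment of the region in a ROH.
.carrier_sets <- function(regions, rohs, samples) {
  lapply(seq_len(nrow(regions)), function(r) {
    hit <- rohs$chr == regions$chr[r] & rohs$pos1 <= regions$start_bp[r] &
      rohs$pos2 >= regions$end_bp[r]
    sort(unique(match(rohs$sample[hit], samples)))
  })
}

# Shared permutation engine: given carrier sets over n samples and a case
# indicator, returns pointwise, max-T corrected and Bonferroni p-values.
.permute_carriers <- function(carrier_sets, is_case, n_perm, chunk = 2000L) {
  R <- length(carrier_sets)
  n <- length(is_case)
  C <- matrix(0, R, n)
  for (r in seq_len(R)) C[r, carrier_sets[[r]]] <- 1
  obs <- as.vector(C %*% is_case)
  S <- matrix(0, R, n_perm)
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    Z <- vapply(seq_len(b), function(k) as.numeric(is_case[sample.int(n)]),
                numeric(n))
    S[, (done + 1L):(done + b)] <- C %*% Z
    done <- done + b
  }
  mu <- rowMeans(S)
  sd <- sqrt(pmax(0, rowMeans(S * S) - mu^2))
  p_point <- (1 + rowSums(S >= obs - 1e-9)) / (1 + n_perm)
  z_obs <- ifelse(sd > 0, (obs - mu) / sd, 0)
  Zs <- (S - mu) / ifelse(sd > 0, sd, 1)
  Zs[sd == 0, ] <- 0
  Mx <- Zs[1L, ]
  if (R > 1L) for (r in 2L:R) Mx <- pmax(Mx, Zs[r, ])
  p_corr <- vapply(seq_len(R), function(r)
    (1 + sum(Mx >= z_obs[r] - 1e-9)) / (1 + n_perm), 0)
  list(obs = obs, p_pointwise = p_point, p_corrected = p_corr,
       p_bonferroni = pmin(1, p_point * R))
}

#' Permutation association test over consensus regions
#'
#' Per-region statistic: the case-carrier count under complete overlap.
#' Pointwise p-values are add-one permutation tail probabilities; the
#' family-wise corrected p-value is the max-T estimate (fraction of
#' permutations in which any region's standardised statistic reaches the
#' region's observed standardised statistic); Bonferroni is also emitted.
#'
#' @param regions data.frame of consensus regions (chr, start_bp, end_bp)
#' @param rohs ROH data frame
#' @param phenotypes named case/control vector
#' @param n_perm permutations (a warning is given below 100)
#' @param seed RNG seed
#' @return \code{regions} with carriers_cases, carriers_controls,
#'   p_pointwise, p_corrected and p_bonferroni columns appended
#' @export
permutation_map <- function(regions, rohs, phenotypes, n_perm = 10000L,
                            seed = 1L) {
  stopifnot(nrow(regions) >= 1L)
  if (n_perm < 100L) warning("n_perm < 100: corrected p-values are unstable")
  ph <- .check_phenotypes(phenotypes)
  ph <- ph[!is.na(ph)]
  samples <- names(ph)
  is_case <- as.numeric(ph == "case")
  set.seed(seed)
  sets <- .carrier_sets(regions, rohs, samples)
  res <- .permute_carriers(sets, is_case, n_perm)
  regions$carriers_cases <- as.integer(res$obs)
  regions$carriers_controls <-
    vapply(sets, length, 0L) - as.integer(res$obs)
  regions$p_pointwise <- res$p_pointwise
  regions$p_corrected <- res$p_corrected
  regions$p_bonferroni <- res$p_bonferroni
  regions
}

#' Gene-based homozygosity mapping
#'
#' Counts, for every gene interval, the individuals whose ROH fully contains
#' the gene (any-overlap counting by flag), and tests case excess by
#' permutation with the gene list as the multiple-testing family. Genes with
#' identical carrier sets are merged into groups: they share a group id and
#' have identical p-values by construction.
#'
#' @param genes interval data.frame (chr, start, end, name) as returned by
#'   \code{\link{read_intervals}}
#' @param rohs ROH data frame (rare set)
#' @param phenotypes named case/control vector
#' @param n_perm permutations
#' @param seed RNG seed
#' @param containment carrier rule: full containment of the gene in a ROH
#'   (default) or any base-pair overlap
#' @return data.frame, one row per gene: carriers, p_pointwise, p_corrected,
#'   p_bonferroni, group_id
#' @export
gene_mapping <- function(genes, rohs, phenotypes, n_perm = 10000L, seed = 1L,
                         containment = TRUE) {
  stopifnot(nrow(genes) >= 1L)
  ph <- .check_phenotypes(phenotypes)
  ph <- ph[!is.na(ph)]
  samples <- names(ph)
  is_case <- as.numeric(ph == "case")
  set.seed(seed)
  sets <- lapply(seq_len(nrow(genes)), function(r) {
    hit <- if (containment)
      rohs$chr == genes$chr[r] & rohs$pos1 <= genes$start[r] &
        rohs$pos2 >= genes$end[r]
    else
      rohs$chr == genes$chr[r] & rohs$pos1 <= genes$end[r] &
        rohs$pos2 >= genes$start[r]
    sort(unique(match(rohs$sample[hit], samples)))
  })
  key <- vapply(sets, paste, "", collapse = ",")
  group_id <- match(key, unique(key))
  # permute once per distinct carrier set; genes in a group share results
  uniq <- !duplicated(key)
  res <- .permute_carriers(sets[uniq], is_case, n_perm)
  idx <- group_id                        # unique sets are indexed in order of appearance
  out <- genes
  out$carriers_cases <- as.integer(res$obs[idx])
  out$carriers_controls <-
    vapply(sets, length, 0L) - out$carriers_cases
  out$p_pointwise <- res$p_pointwise[idx]
  # family-wise correction must span the full gene list; identical carrier
  # sets contribute one distinct statistic, so max-T over unique sets equals
  # max-T over all genes
  out$p_corrected <- res$p_corrected[idx]
  out$p_bonferroni <- pmin(1, res$p_pointwise[idx] * nrow(genes))
  out$group_id <- group_id
  out
}
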
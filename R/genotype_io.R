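# Readers and writers for every on-disk format the pipeline touches:
# PLINK text genotypes (PED/MAP), ROH tables, interval lists, covariates.
#
# Internal coordinate convention: 1-based, inclusive at both ends. BED input
# (0-based half-open) is converted on read. Genotypes are stored as minor-
# allele dosage codes: 0 = homozygous major (A), 1 = heterozygous,
# 2 = homozygous minor (B), NA = missing. Allele orientation is irrelevant to
# every downstream computation (only het/hom/missing status is used) but is
# recorded so that write -> read round trips are identities.

#' Construct a genotype dataset
#'
#' The universal input container of the pipeline: a samples x SNPs genotype
#' matrix, the variant map, per-sample phenotypes and (optionally) the allele
#' labels and PLINK family fields needed for faithful PED/MAP round trips.
#'
#' @param geno integer matrix, samples in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\} counting minor-allele copies. Row names are sample ids,
#'   column names SNP ids.
#' @param map data.frame with columns \code{chr} (autosome 1-22),
#'   \code{snp_id}, \code{bp} (1-based position). Positions must be strictly
#'   increasing within each chromosome.
#' @param phenotype character vector aligned with rows of \code{geno};
#'   values \code{"case"}, \code{"control"} or NA.
#' @param alleles optional data.frame with columns \code{a1} (major) and
#'   \code{a2} (minor) per SNP; NA where an allele was never observed.
#' @param fam optional data.frame of PLINK family fields
#'   (\code{fid, iid, pat, mat, sex}) kept for round trips.
#' @return an object of class \code{genotype_dataset}
#' @export
genotype_dataset <- function(geno, map, phenotype, alleles = NULL, fam = NULL) {
  if (!is.matrix(geno)) stop("geno must be a matrix")
  storage.mode(geno) <- "integer"
  if (nrow(map) != ncol(geno))
    stop(sprintf("map has %d variants but genotype matrix has %d columns",
                 nrow(map), ncol(geno)))
  map$chr <- .check_autosomes(map$chr)
  map$bp <- as.numeric(map$bp)
  if (anyDuplicated(map$snp_id)) stop("duplicated SNP ids in map")
  for (c in unique(map$chr)) {
    bp <- map$bp[map$chr == c]
    if (any(diff(bp) <= 0))
      stop(sprintf("bp positions not strictly increasing on chromosome %d", c))
  }
  if (length(phenotype) != nrow(geno))
    stop("phenotype length does not match sample count")
  phenotype <- as.character(phenotype)
  if (nrow(geno) > 0L && is.null(rownames(geno)))
    stop("geno must have sample ids as row names")
  if (is.null(rownames(geno))) rownames(geno) <- character(0)
  if (anyDuplicated(rownames(geno))) stop("duplicated sample ids")
  colnames(geno) <- map$snp_id
  if (is.null(alleles))
    alleles <- data.frame(a1 = rep(NA_character_, nrow(map)),
                          a2 = rep(NA_character_, nrow(map)),
                          stringsAsFactors = FALSE)
  if (is.null(fam))
    fam <- data.frame(fid = rownames(geno), iid = rownames(geno),
                      pat = rep("0", nrow(geno)), mat = rep("0", nrow(geno)),
                      sex = rep("0", nrow(geno)), stringsAsFactors = FALSE)
  structure(list(geno = geno, map = map, phenotype = phenotype,
                 alleles = alleles, fam = fam),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs on %d autosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  tab <- table(factor(x$phenotype, levels = c("case", "control")), useNA = "ifany")
  cat(sprintf("  cases: %d  controls: %d  missing phenotype: %d\n",
              tab[["case"]], tab[["control"]], sum(is.na(x$phenotype))))
  cat(sprintf("  missing genotype rate: %.4f\n", mean(is.na(x$geno))))
  invisible(x)
}

#' Sample ids of a genotype dataset
#' @param dataset a \code{genotype_dataset}
#' @return character vector
#' @export
sample_ids <- function(dataset) rownames(dataset$geno)

#' Named phenotype vector of a genotype dataset
#' @param dataset a \code{genotype_dataset}
#' @return character vector named by sample id, values case/control/NA
#' @export
phenotypes_of <- function(dataset) {
  stats::setNames(dataset$phenotype, rownames(dataset$geno))
}

# Re-orient genotype codes so that the minor allele (by empirical frequency,
# ties broken toward the lexicographically larger allele label) is coded 2.
# The reader applies the same rule, making write -> read an identity.
normalize_orientation <- function(dataset) {
  g <- dataset$geno
  n2 <- colSums(g, na.rm = TRUE)                 # minor allele copies
  nn <- colSums(!is.na(g))
  flip <- n2 > nn |                              # freq(B) > 0.5
    (n2 == nn & !is.na(dataset$alleles$a2) & !is.na(dataset$alleles$a1) &
       dataset$alleles$a2 < dataset$alleles$a1)  # tie: larger label is minor
  if (any(flip)) {
    g[, flip] <- 2L - g[, flip]
    a1 <- dataset$alleles$a1
    dataset$alleles$a1[flip] <- dataset$alleles$a2[flip]
    dataset$alleles$a2[flip] <- a1[flip]
    dataset$geno <- g
  }
  dataset
}

#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses a whitespace-delimited PED/MAP pair. Genotype codes are oriented by
#' per-SNP allele frequency (minor allele = code 2); \code{"0 0"} allele pairs
#' become missing; phenotype column 2 maps to case, 1 to control, anything
#' else to missing. Non-autosomal variants are dropped with a message.
#'
#' @param ped_path,map_path paths to the .ped and .map files
#' @return a \code{genotype_dataset}
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = c("character", "character",
                                              "character", "numeric"),
                               col.names = c("chr", "snp_id", "cm", "bp"))
  chr_int <- suppressWarnings(as.integer(map_raw$chr))
  keep <- !is.na(chr_int) & chr_int >= 1L & chr_int <= 22L
  if (any(!keep))
    message(sprintf("read_plink_text: dropped %d non-autosomal variant(s)", sum(!keep)))
  n_all <- nrow(map_raw)
  map <- data.frame(chr = chr_int[keep], snp_id = map_raw$snp_id[keep],
                    bp = map_raw$bp[keep], stringsAsFactors = FALSE)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n_field <- 6L + 2L * n_all
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != n_field)
      stop(sprintf("PED row %d has %d fields, expected %d (6 + 2 x %d map variants)",
                   i, length(toks[[i]]), n_field, n_all))
  }
  n <- length(toks)
  m <- nrow(map)
  fam <- data.frame(
    fid = vapply(toks, `[`, "", 1L), iid = vapply(toks, `[`, "", 2L),
    pat = vapply(toks, `[`, "", 3L), mat = vapply(toks, `[`, "", 4L),
    sex = vapply(toks, `[`, "", 5L), stringsAsFactors = FALSE)
  phen_code <- vapply(toks, `[`, "", 6L)
  phenotype <- ifelse(phen_code == "2", "case",
                      ifelse(phen_code == "1", "control", NA_character_))
  ids <- fam$iid
  if (anyDuplicated(ids)) ids <- paste(fam$fid, fam$iid, sep = ":")
  if (anyDuplicated(ids)) stop("duplicated FID:IID sample identifiers in PED")

  kept_idx <- which(keep)
  a_col1 <- 5L + 2L * kept_idx   # first allele field of each kept variant
  al1 <- matrix("", n, m); al2 <- matrix("", n, m)
  for (i in seq_len(n)) {
    al1[i, ] <- toks[[i]][a_col1]
    al2[i, ] <- toks[[i]][a_col1 + 1L]
  }
  geno <- matrix(NA_integer_, n, m, dimnames = list(ids, map$snp_id))
  alleles <- data.frame(a1 = rep(NA_character_, m), a2 = rep(NA_character_, m),
                        stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    x1 <- al1[, j]; x2 <- al2[, j]
    ok <- x1 != "0" & x2 != "0"
    obs <- c(x1[ok], x2[ok])
    if (!length(obs)) next                      # all-missing SNP
    cnt <- sort(table(obs))
    labs <- names(cnt)
    if (length(labs) > 2L)
      stop(sprintf("SNP %s has more than two alleles", map$snp_id[j]))
    if (length(labs) == 1L) {
      a_major <- labs; a_minor <- NA_character_
    } else {
      # minor = least frequent; tie broken toward the larger label
      if (cnt[[1L]] == cnt[[2L]]) labs <- sort(labs)   # larger label last => minor
      a_minor <- labs[if (cnt[[1L]] == cnt[[2L]]) 2L else 1L]
      a_major <- setdiff(labs, a_minor)
    }
    alleles$a1[j] <- a_major; alleles$a2[j] <- a_minor
    code <- rep(NA_integer_, n)
    if (is.na(a_minor)) {
      code[ok] <- 0L
    } else {
      code[ok] <- (x1[ok] == a_minor) + (x2[ok] == a_minor)
    }
    geno[, j] <- code
  }
  genotype_dataset(geno, map, phenotype, alleles = alleles, fam = fam)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Inverse of \code{\link{read_plink_text}}: the emitted pair round-trips to
#' an identical \code{genotype_dataset} (same codes, map, phenotypes).
#'
#' @param dataset a \code{genotype_dataset}
#' @param prefix output path prefix; \code{<prefix>.ped} and
#'   \code{<prefix>.map} are written
#' @return invisibly, the two file paths
#' @export
write_plink_text <- function(dataset, prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  map <- dataset$map
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, format(map$bp, scientific = FALSE, trim = TRUE)),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  g <- dataset$geno
  n <- nrow(g); m <- ncol(g)
  a1 <- dataset$alleles$a1; a2 <- dataset$alleles$a2
  a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
  phen <- ifelse(is.na(dataset$phenotype), "-9",
                 ifelse(dataset$phenotype == "case", "2", "1"))
  con <- file(ped_path, open = "wt")
  on.exit(close(con))
  fam <- dataset$fam
  for (i in seq_len(n)) {
    gi <- g[i, ]
    x1 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, a2, a1))
    x2 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, a2, a1))
    writeLines(paste(c(fam$fid[i], fam$iid[i], fam$pat[i], fam$mat[i],
                       fam$sex[i], phen[i], as.vector(rbind(x1, x2))),
                     collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Write a ROH table
#'
#' Tab-delimited table with the PLINK .hom-style column layout:
#' SAMPLE, PHENOTYPE, CHR, SNP1, SNP2, POS1, POS2, KB, NSNP, DENSITY.
#' KB is (POS2 - POS1 + 1)/1000. Numeric columns are written with full
#' precision so that \code{\link{read_roh_table}} recovers them exactly.
#'
#' @param rohs ROH data frame as produced by \code{\link{detect_roh}}
#' @param path output file path
#' @return invisibly, \code{path}
#' @export
write_roh_table <- function(rohs, path) {
  .check_roh(rohs)
  out <- data.frame(
    SAMPLE = rohs$sample,
    PHENOTYPE = ifelse(is.na(rohs$phenotype), "NA", rohs$phenotype),
    CHR = rohs$chr,
    SNP1 = rohs$snp1, SNP2 = rohs$snp2,
    POS1 = format(rohs$pos1, scientific = FALSE, trim = TRUE),
    POS2 = format(rohs$pos2, scientific = FALSE, trim = TRUE),
    KB = sprintf("%.17g", rohs$kb),
    NSNP = rohs$nsnp,
    DENSITY = sprintf("%.17g", rohs$density),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ROH table written by \code{\link{write_roh_table}}
#'
#' @param path file path
#' @return ROH data frame with the package's internal (lower-case) columns
#' @export
read_roh_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character", "integer",
                                        "character", "character", "numeric",
                                        "numeric", "numeric", "integer",
                                        "numeric"),
                         stringsAsFactors = FALSE)
  if (!nrow(x)) return(.empty_roh()[, 1:10])
  data.frame(sample = x$SAMPLE,
             phenotype = ifelse(x$PHENOTYPE == "NA", NA_character_, x$PHENOTYPE),
             chr = x$CHR, snp1 = x$SNP1, snp2 = x$SNP2,
             pos1 = x$POS1, pos2 = x$POS2, kb = x$KB, nsnp = x$NSNP,
             density = x$DENSITY, stringsAsFactors = FALSE)
}

#' Read an interval list (genes, loci)
#'
#' Accepts 3- or 4-column whitespace/tab-delimited input (chromosome, start,
#' end, optional name). Intervals are normalised to the package convention of
#' 1-based inclusive coordinates; BED input (0-based half-open) is shifted on
#' read. When several intervals share a name only the longest is kept, the
#' usual rule when collapsing transcripts to one reference interval per gene.
#'
#' @param path file path
#' @param convention \code{"one_inclusive"} (default) or \code{"bed0half"}
#' @return data.frame with columns chr, start, end, name
#' @export
read_intervals <- function(path, convention = c("one_inclusive", "bed0half")) {
  convention <- match.arg(convention)
  raw <- tryCatch(utils::read.table(path, header = FALSE, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || !nrow(raw))
    return(data.frame(chr = integer(), start = numeric(), end = numeric(),
                      name = character(), stringsAsFactors = FALSE))
  if (ncol(raw) < 3L) stop("interval file must have at least 3 columns")
  name <- if (ncol(raw) >= 4L) as.character(raw[[4L]]) else
    sprintf("iv%d", seq_len(nrow(raw)))
  chr_int <- suppressWarnings(as.integer(gsub("^chr", "", as.character(raw[[1L]]))))
  keep <- !is.na(chr_int) & chr_int >= 1L & chr_int <= 22L
  if (any(!keep))
    message(sprintf("read_intervals: dropped %d non-autosomal interval(s)", sum(!keep)))
  start <- as.numeric(raw[[2L]]); end <- as.numeric(raw[[3L]])
  if (convention == "bed0half") start <- start + 1
  bad <- which(keep & start > end)
  if (length(bad))
    stop(sprintf("interval start > end after normalisation at line %d", bad[1L]))
  iv <- data.frame(chr = chr_int[keep], start = start[keep], end = end[keep],
                   name = name[keep], stringsAsFactors = FALSE)
  # longest interval per name
  if (anyDuplicated(iv$name)) {
    len <- iv$end - iv$start + 1
    ord <- order(iv$name, -len)
    iv <- iv[ord, , drop = FALSE]
    iv <- iv[!duplicated(iv$name), , drop = FALSE]
  }
  iv <- iv[order(iv$chr, iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Read a covariate table
#'
#' TSV with header; must contain \code{sample_id}, other columns (phenotype,
#' age, aao, cohort, f, C1, C2, ...) are passed through.
#'
#' @param path file path
#' @return data.frame
#' @export
read_covariates <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(x)) stop("covariate table lacks a sample_id column")
  if ("age" %in% names(x) && any(x$age < 0, na.rm = TRUE)) stop("negative age")
  if ("aao" %in% names(x) && any(x$aao < 0, na.rm = TRUE)) stop("negative aao")
  x
}

#' Write a covariate table
#' @param covariates data.frame with a sample_id column
#' @param path file path
#' @return invisibly, \code{path}
#' @export
write_covariates <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
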
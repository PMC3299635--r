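# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population standard deviation
#'
#' Standard deviation with the population formula (divide by n, not n-1).
#' Region length statistics in the common/rare filter use this form so that
#' the retention cutoff is fully determined by the overlapping lengths.
#'
#' @param x numeric vector
#' @return scalar standard deviation; 0 for length-1 input
#' @export
pop_sd <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

# Comparison tolerance used when counting permuted statistics >= observed.
.perm_tol <- function(obs) 1e-9 * max(1, abs(obs))

# Stop unless all chromosome labels are autosomal integers 1..22.
.check_autosomes <- function(chr, what = "chromosome") {
  ch <- suppressWarnings(as.integer(chr))
  if (anyNA(ch) || any(ch < 1L | ch > 22L)) {
    stop(sprintf("non-autosomal or unparseable %s label(s): %s",
                 what, paste(utils::head(unique(chr[is.na(ch) | ch < 1 | ch > 22]), 5), collapse = ", ")),
         call. = FALSE)
  }
  ch
}

# Empty ROH table with the canonical column layout.
.empty_roh <- function() {
  data.frame(sample = character(), phenotype = character(), chr = integer(),
             snp1 = character(), snp2 = character(),
             pos1 = numeric(), pos2 = numeric(), kb = numeric(),
             nsnp = integer(), density = numeric(),
             nhet = integer(), nmiss = integer(),
             stringsAsFactors = FALSE)
}

# Validate a ROH data frame has at least the core columns.
.check_roh <- function(rohs) {
  need <- c("sample", "chr", "pos1", "pos2", "kb")
  miss <- setdiff(need, names(rohs))
  if (length(miss))
    stop("ROH table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  invisible(rohs)
}

# Named case/control phenotype vector from various inputs; names = sample ids.
.check_phenotypes <- function(phenotypes) {
  if (is.null(names(phenotypes)))
    stop("phenotypes must be a named vector (names = sample ids)", call. = FALSE)
  ph <- as.character(phenotypes)
  names(ph) <- names(phenotypes)
  bad <- !is.na(ph) & !ph %in% c("case", "control")
  if (any(bad))
    stop("phenotype values must be 'case', 'control' or NA", call. = FALSE)
  ph
}
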
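# Internal helpers shared across modules.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Null-coalescing operator
#' @param a,b values; `b` is returned when `a` is NULL
#' @return `a` unless it is NULL, else `b`
#' @export
#' @name op-null-default
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base [round()] uses round-half-to-even; panel percentages follow the
#' conventional half-up rule so that e.g. 71.45 -> 71.5 at one decimal.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Round half-up to a number of significant figures
#'
#' @param x numeric vector
#' @param sig significant figures (>= 1)
#' @return rounded numeric vector
#' @export
signif_half_up <- function(x, sig = 2) {
  stopifnot(sig >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  d <- sig - 1 - floor(log10(abs(x[nz])))
  out[nz] <- round_half_up(x[nz], d)
  out
}

# Validate a character scalar is a canonical amino-acid sequence.
check_aa <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  }
  bad <- setdiff(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (length(bad)) {
    stop(what, " contains non-canonical residue(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

# Deterministic TSV writers: no quoting surprises, "." as NA is never used.
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA",
                     scipen = 50)
  invisible(path)
}

read_tsv <- function(path, ...) {
  data.table::fread(path, sep = "\t", header = TRUE, colClasses = NULL,
                    na.strings = "NA", data.table = TRUE, ...)
}

# Length of the intersection of two 1-based inclusive intervals (0 if disjoint).
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}
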
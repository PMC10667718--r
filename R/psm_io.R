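# PSM (peptide-spectrum match) table interchange format.
#
# The canonical format is a flat TSV with a fixed column set, deliberately
# engine-agnostic (search-engine exports vary; mzIdentML is out of scope):
#   sample_id donor_id day analyst peptide charge xcorr mods proteins is_decoy
#
# Modification grammar, one token per modification, ";"-separated:
#   <residue><position>(<ox|deam>)   e.g.  M4(ox);N7(deam)
# with "?" as the position of an unlocalized modification: N?(deam).
# Localization status must survive the round trip because localized and
# unlocalized deamidation are reported (and colored) differently downstream.

PSM_COLUMNS <- c("sample_id", "donor_id", "day", "analyst", "peptide",
                 "charge", "xcorr", "mods", "proteins", "is_decoy")

#' Fixed modification mass deltas (Da)
#'
#' Methionine oxidation adds +15.995 Da; asparagine/glutamine deamidation
#' adds +0.984 Da. These are properties of the modification kind, not of
#' individual records.
#' @export
MOD_MASS <- c(MetOx = 15.995, Deamidation = 0.984)

mod_token_re <- "^([MNQ])([0-9]+|\\?)\\((ox|deam)\\)$"

#' Parse a modification string into a modification table
#'
#' @param mods a single mods string (possibly ""), e.g. `"M4(ox);N?(deam)"`
#' @return data.frame with columns `kind` (MetOx/Deamidation), `residue`,
#'   `position` (integer, NA when unlocalized), `localized`, `mass_delta`
#' @export
parse_mods <- function(mods) {
  if (is.na(mods) || !nzchar(mods)) {
    return(data.frame(kind = character(), residue = character(),
                      position = integer(), localized = logical(),
                      mass_delta = numeric()))
  }
  toks <- strsplit(mods, ";", fixed = TRUE)[[1]]
  m <- regmatches(toks, regexec(mod_token_re, toks))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop("malformed modification token: ", toks[bad][1], call. = FALSE)
  }
  res <- vapply(m, `[`, "", 2L)
  pos <- vapply(m, `[`, "", 3L)
  tag <- vapply(m, `[`, "", 4L)
  kind <- ifelse(tag == "ox", "MetOx", "Deamidation")
  ok <- (kind == "MetOx" & res == "M") |
    (kind == "Deamidation" & res %in% c("N", "Q"))
  if (!all(ok)) {
    stop("modification kind/residue mismatch in token: ",
         toks[!ok][1], call. = FALSE)
  }
  data.frame(kind = kind, residue = res,
             position = ifelse(pos == "?", NA_integer_,
                               suppressWarnings(as.integer(pos))),
             localized = pos != "?",
             mass_delta = unname(MOD_MASS[kind]))
}

#' Serialize a modification table back to the mods string
#'
#' @param mod_df data.frame as returned by [parse_mods()]
#' @return character scalar ("" when no modifications)
#' @export
format_mods <- function(mod_df) {
  if (nrow(mod_df) == 0) return("")
  tag <- ifelse(mod_df$kind == "MetOx", "ox", "deam")
  pos <- ifelse(is.na(mod_df$position), "?", as.character(mod_df$position))
  paste0(mod_df$residue, pos, "(", tag, ")", collapse = ";")
}

#' Number of modifications per record (vectorized)
#'
#' An unlocalized modification counts exactly once per token: a modification
#' is a modification regardless of localization confidence.
#'
#' @param mods character vector of mods strings
#' @return integer vector
#' @export
count_mods <- function(mods) {
  n <- lengths(strsplit(mods, ";", fixed = TRUE))
  n[is.na(mods) | !nzchar(mods)] <- 0L
  as.integer(n)
}

# Validate a PSM data.table in place; `line` gives the file line of each row
# for error reporting (NULL when the table was built in code).
validate_psm_table <- function(dt, line = NULL) {
  if (is.null(line)) line <- seq_len(nrow(dt)) + 1L
  where <- function(i) {
    if (is.na(line[i])) paste0("record ", i) else paste0("line ", line[i])
  }
  if (nrow(dt) == 0) return(invisible(dt))

  bad <- which(is.na(dt$peptide) | !nzchar(dt$peptide) |
                 grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                       dt$peptide))
  if (length(bad)) {
    stop("invalid peptide sequence at ", where(bad[1]), call. = FALSE)
  }
  bad <- which(is.na(dt$charge) | dt$charge < 2L | dt$charge > 7L)
  if (length(bad)) {
    stop("charge outside the accepted 2-7 precursor charge range at ",
         where(bad[1]), call. = FALSE)
  }
  bad <- which(is.na(dt$xcorr) | dt$xcorr < 0)
  if (length(bad)) stop("negative xcorr at ", where(bad[1]), call. = FALSE)
  bad <- which(is.na(dt$is_decoy))
  if (length(bad)) stop("missing is_decoy at ", where(bad[1]), call. = FALSE)

  has_mods <- which(!is.na(dt$mods) & nzchar(dt$mods))
  for (i in has_mods) {
    md <- tryCatch(parse_mods(dt$mods[i]),
                   error = function(e) stop(conditionMessage(e), " at ",
                                            where(i), call. = FALSE))
    loc <- md[md$localized, , drop = FALSE]
    if (nrow(loc)) {
      if (any(loc$position > nchar(dt$peptide[i]))) {
        stop("localized modification position beyond peptide length at ",
             where(i), call. = FALSE)
      }
      at <- substring(dt$peptide[i], loc$position, loc$position)
      if (any(at != loc$residue)) {
        stop("modification residue does not match peptide at ",
             where(i), call. = FALSE)
      }
    }
  }
  invisible(dt)
}

#' Read a PSM table
#'
#' Parsing is total: every row either yields a validated record or a
#' located error (file line number); rows are never silently dropped.
#' Row order is preserved.
#'
#' @param path TSV path with the exact column set
#'   `sample_id, donor_id, day, analyst, peptide, charge, xcorr, mods,
#'   proteins, is_decoy`
#' @return a `data.table` with those columns
#' @export
read_psm_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(
                            character = c("sample_id", "donor_id", "day",
                                          "analyst", "peptide", "mods",
                                          "proteins"),
                            integer = "charge", numeric = "xcorr",
                            logical = "is_decoy"),
                          na.strings = NULL, data.table = TRUE)
  unknown <- setdiff(names(dt), PSM_COLUMNS)
  if (length(unknown)) {
    stop("unknown column(s) in PSM table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(PSM_COLUMNS, names(dt))
  if (length(missing)) {
    stop("missing column(s) in PSM table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data.table::setcolorder(dt, PSM_COLUMNS)
  validate_psm_table(dt)
  dt[]
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: `read_psm_table(write_psm_table(x))`
#' reproduces `x` exactly.
#'
#' @param records a data.frame/data.table with the PSM column set
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_psm_table <- function(records, path) {
  dt <- data.table::as.data.table(records)
  missing <- setdiff(PSM_COLUMNS, names(dt))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_psm_table(dt, line = rep(NA_integer_, nrow(dt)))
  data.table::fwrite(dt[, PSM_COLUMNS, with = FALSE], path, sep = "\t",
                     quote = FALSE, logical01 = FALSE, scipen = 50)
  invisible(path)
}
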
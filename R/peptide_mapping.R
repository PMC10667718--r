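# Mapping accepted peptides onto the therapeutic chains.
#
# Because spectra are searched with no enzyme specificity, any contiguous
# substring of a chain is a legal placement; all placements (including
# overlapping ones and multi-chain hits) are retained.

match_seq <- function(s, match_mode) {
  # MS cannot distinguish Ile from Leu; il_equivalent folds both to L
  if (match_mode == "il_equivalent") chartr("I", "L", s) else s
}

# All (start, end) placements of `pattern` in `subject` (both plain strings),
# including overlapping occurrences.
find_placements <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) {
    return(integer(0))
  }
  m <- Biostrings::matchPattern(pattern, Biostrings::AAString(subject))
  Biostrings::start(m)
}

#' Map one peptide onto a therapeutic molecule
#'
#' @param peptide amino-acid string
#' @param molecule a [therapeutic_molecule()]
#' @param match_mode `"exact"` (default: search engines report
#'   database-derived sequences, so a therapeutic peptide matches the
#'   construct exactly) or `"il_equivalent"` (I and L treated as identical)
#' @return data.frame of placements with columns `chain_id`, `start`, `end`;
#'   zero rows when the peptide is not therapeutic-derived
#' @export
map_peptide <- function(peptide, molecule,
                        match_mode = c("exact", "il_equivalent")) {
  match_mode <- match.arg(match_mode)
  check_aa(peptide, "peptide")
  p <- match_seq(peptide, match_mode)
  out <- lapply(c("HC", "LC"), function(ch) {
    st <- find_placements(p, match_seq(molecule$chains[[ch]], match_mode))
    if (!length(st)) return(NULL)
    data.frame(chain_id = ch, start = as.integer(st),
               end = as.integer(st + nchar(peptide) - 1L))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chain_id = character(), start = integer(),
                      end = integer())
  }
  out
}

#' CDR regions overlapped by a placement
#'
#' A placement overlaps a CDR when they share at least one residue; no
#' minimum-overlap fraction is applied (clusters are labelled as CDR-region
#' clusters by any span into the CDR).
#'
#' @param chain_id,start,end the placement (1-based inclusive)
#' @param molecule a [therapeutic_molecule()]
#' @return character vector of CDR names (possibly empty), in CDR order
#' @export
annotate_cdr_overlap <- function(chain_id, start, end, molecule) {
  cdrs <- molecule$cdrs
  hit <- cdrs$chain_id == chain_id &
    interval_overlap(cdrs$start, cdrs$end, start, end) >= 1L
  cdrs$name[hit]
}

#' Is a peptide unique to the therapeutic?
#'
#' TRUE iff the peptide occurs in at least one therapeutic chain and in no
#' background protein under the same matching mode. A peptide absent from
#' the therapeutic is not "unique to" it and returns FALSE.
#'
#' @param peptide amino-acid string
#' @param molecule a [therapeutic_molecule()]
#' @param background an `AAStringSet` (see [load_background()]) or character
#'   vector of background protein sequences
#' @param match_mode as in [map_peptide()]
#' @return logical scalar
#' @export
is_unique_to_therapeutic <- function(peptide, molecule, background,
                                     match_mode = c("exact",
                                                    "il_equivalent")) {
  match_mode <- match.arg(match_mode)
  if (nrow(map_peptide(peptide, molecule, match_mode)) == 0) return(FALSE)
  bg <- match_seq(as.character(background), match_mode)
  p <- match_seq(peptide, match_mode)
  !any(grepl(p, bg, fixed = TRUE))
}

#' Load a background proteome FASTA
#'
#' @param path FASTA of background (self) protein sequences
#' @return an `AAStringSet`
#' @export
load_background <- function(path) Biostrings::readAAStringSet(path)

#' Map all accepted peptides of a PSM table onto a molecule
#'
#' One output row per (distinct placement of a) PSM record; records whose
#' peptide does not occur in either chain are dropped (they are background,
#' not therapeutic). Localized modification positions are lifted from
#' peptide coordinates to chain coordinates.
#'
#' @param records accepted PSM records (see [apply_filters()]); a `tier`
#'   column is required
#' @param molecule a [therapeutic_molecule()]
#' @param background optional background proteome for the uniqueness flag
#' @param match_mode as in [map_peptide()]
#' @return data.table of mapped peptides: sample_id, donor_id, day, analyst,
#'   peptide, charge, xcorr, mods, tier, chain_id, start, end, cdrs
#'   (";"-joined names), unique_to_therapeutic
#' @export
map_panel <- function(records, molecule, background = NULL,
                      match_mode = c("exact", "il_equivalent")) {
  match_mode <- match.arg(match_mode)
  dt <- data.table::as.data.table(records)
  empty <- data.table::data.table(
    sample_id = character(), donor_id = character(), day = character(),
    analyst = character(), peptide = character(), charge = integer(),
    xcorr = numeric(), mods = character(), tier = character(),
    chain_id = character(), start = integer(), end = integer(),
    cdrs = character(), unique_to_therapeutic = logical())
  if (nrow(dt) == 0) return(empty)
  if (!"tier" %in% names(dt)) {
    stop("records must carry a tier column (run apply_filters first)",
         call. = FALSE)
  }

  peps <- unique(dt$peptide)
  # fast prefilter: the overwhelming majority of accepted peptides are
  # background; only chain hits need full (overlapping) placement search
  hc <- match_seq(molecule$chains$HC, match_mode)
  lc <- match_seq(molecule$chains$LC, match_mode)
  pp <- match_seq(peps, match_mode)
  cand <- vapply(pp, function(p) {
    grepl(p, hc, fixed = TRUE) || grepl(p, lc, fixed = TRUE)
  }, TRUE, USE.NAMES = FALSE)
  placements <- vector("list", length(peps))
  placements[cand] <- lapply(peps[cand], map_peptide, molecule = molecule,
                             match_mode = match_mode)
  placements[!cand] <- list(data.frame(chain_id = character(),
                                       start = integer(), end = integer()))
  n_pl <- vapply(placements, nrow, 1L)
  if (sum(n_pl) == 0) return(empty)
  pl <- data.table::as.data.table(do.call(rbind, placements))
  pl[, peptide := rep(peps, n_pl)]
  pl[, cdrs := mapply(function(ch, s, e) {
    paste(annotate_cdr_overlap(ch, s, e, molecule), collapse = ";")
  }, chain_id, start, end)]
  if (!is.null(background)) {
    # only peptides with a placement need the (expensive) uniqueness check
    placed <- unique(pl$peptide)
    uniq <- vapply(placed, is_unique_to_therapeutic, TRUE,
                   molecule = molecule, background = background,
                   match_mode = match_mode)
    pl[, unique_to_therapeutic := uniq[match(peptide, placed)]]
  } else {
    pl[, unique_to_therapeutic := NA]
  }

  keep <- c("sample_id", "donor_id", "day", "analyst", "peptide", "charge",
            "xcorr", "mods")
  out <- merge(dt[, c(keep, "tier"), with = FALSE], pl, by = "peptide",
               allow.cartesian = TRUE, sort = FALSE)
  out[, tier := as.character(tier)]
  # lift localized modification positions into chain coordinates
  out[, mods_chain := mapply(function(m, s) {
    md <- parse_mods(m)
    if (nrow(md) == 0) return("")
    md$position <- md$position + s - 1L
    format_mods(md)
  }, mods, start)]
  data.table::setcolorder(out, c("sample_id", "donor_id", "day", "analyst",
                                 "peptide", "charge", "xcorr", "mods",
                                 "tier", "chain_id", "start", "end", "cdrs",
                                 "unique_to_therapeutic", "mods_chain"))
  data.table::setorder(out, sample_id, chain_id, start, end, peptide)
  out[]
}

#' Peptide length statistics
#'
#' The median uses the lower-median convention for even counts (the smaller
#' of the two central order statistics), so the reported value is always an
#' observed peptide length.
#'
#' @param mapped data.frame with a `peptide` column (or character vector of
#'   peptides); lengths are computed over distinct peptide sequences
#' @return list with `n`, `median` (NA when empty) and `histogram`
#'   (data.frame length/count)
#' @export
length_statistics <- function(mapped) {
  peps <- if (is.character(mapped)) mapped else mapped$peptide
  peps <- unique(peps)
  if (length(peps) == 0) {
    return(list(n = 0L, median = NA_integer_,
                histogram = data.frame(length = integer(), count = integer())))
  }
  len <- sort(nchar(peps))
  med <- len[ceiling(length(len) / 2)]  # lower median for even n
  tab <- table(len)
  list(n = length(len), median = as.integer(med),
       histogram = data.frame(length = as.integer(names(tab)),
                              count = as.integer(tab)))
}
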
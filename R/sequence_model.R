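# Therapeutic antibody chains, CDR annotation, and region utilities.
#
# All coordinates in this package are 1-based and inclusive, matching the
# residue numbering used when clusters are described as e.g. "HC 73-92".

#' Construct a therapeutic molecule
#'
#' A therapeutic monoclonal antibody is represented by exactly one heavy
#' chain (`HC`) and one light chain (`LC`), each an amino-acid string over
#' the canonical 20-letter alphabet, plus user-supplied CDR intervals in the
#' molecule's own 1-based inclusive numbering. No numbering scheme
#' (Kabat/IMGT/Chothia) is applied: CDR intervals are taken as given.
#'
#' @param name molecule name
#' @param hc,lc heavy / light chain amino-acid sequences
#' @param cdrs data.frame with columns `chain_id` ("HC"/"LC"), `name`
#'   (unique per chain, e.g. "HC CDR2"), `start`, `end` (1-based inclusive).
#'   May be empty.
#' @param ada_rate_text optional free-text clinical anti-drug-antibody rate
#'   (metadata only, e.g. "5-26%")
#' @return an object of class `therapeutic_molecule`
#' @export
therapeutic_molecule <- function(name, hc, lc, cdrs = NULL,
                                 ada_rate_text = NULL) {
  check_aa(hc, "HC sequence")
  check_aa(lc, "LC sequence")
  if (is.null(cdrs)) {
    cdrs <- data.frame(chain_id = character(), name = character(),
                       start = integer(), end = integer())
  }
  cdrs <- as.data.frame(cdrs)[, c("chain_id", "name", "start", "end")]
  cdrs$start <- as.integer(cdrs$start)
  cdrs$end <- as.integer(cdrs$end)
  mol <- structure(
    list(name = name,
         chains = list(HC = hc, LC = lc),
         cdrs = cdrs,
         ada_rate_text = ada_rate_text),
    class = "therapeutic_molecule")
  validate_molecule(mol)
  mol
}

validate_molecule <- function(mol) {
  cdrs <- mol$cdrs
  if (nrow(cdrs) == 0) return(invisible(mol))
  if (anyNA(cdrs$start) || anyNA(cdrs$end)) {
    stop("CDR intervals contain missing coordinates", call. = FALSE)
  }
  if (!all(cdrs$chain_id %in% c("HC", "LC"))) {
    stop("CDR chain_id must be HC or LC", call. = FALSE)
  }
  for (ch in unique(cdrs$chain_id)) {
    sub <- cdrs[cdrs$chain_id == ch, , drop = FALSE]
    len <- nchar(mol$chains[[ch]])
    if (any(sub$start < 1L | sub$end > len | sub$start > sub$end)) {
      stop("CDR interval out of bounds on ", ch, " (length ", len, ")",
           call. = FALSE)
    }
    if (anyDuplicated(sub$name)) {
      stop("duplicate CDR name on ", ch, call. = FALSE)
    }
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      stop("overlapping CDR intervals on ", ch, call. = FALSE)
    }
  }
  invisible(mol)
}

#' @export
print.therapeutic_molecule <- function(x, ...) {
  cat(sprintf("<therapeutic_molecule> %s\n", x$name))
  cat(sprintf("  HC: %d aa, %d CDR(s)\n", nchar(x$chains$HC),
              sum(x$cdrs$chain_id == "HC")))
  cat(sprintf("  LC: %d aa, %d CDR(s)\n", nchar(x$chains$LC),
              sum(x$cdrs$chain_id == "LC")))
  if (!is.null(x$ada_rate_text)) {
    cat(sprintf("  reported clinical ADA rate: %s\n", x$ada_rate_text))
  }
  invisible(x)
}

#' Load a therapeutic molecule from FASTA plus a CDR region sidecar
#'
#' The FASTA must contain exactly one record whose header carries the token
#' `|HC` and one with `|LC` (e.g. `>mab1|HC`). The sidecar is tab-separated
#' with columns `chain_id`, `region_name`, `start`, `end` in the molecule's
#' 1-based inclusive numbering.
#'
#' @param fasta_path path to the chain FASTA
#' @param regions_path path to the CDR sidecar TSV (NULL for no CDRs)
#' @param name molecule name; default: FASTA header prefix of the HC record
#' @return a [therapeutic_molecule()]
#' @export
load_therapeutic <- function(fasta_path, regions_path = NULL, name = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  hdr <- names(seqs)
  role <- rep(NA_character_, length(seqs))
  role[grepl("\\|HC\\b", hdr)] <- "HC"
  role[grepl("\\|LC\\b", hdr)] <- "LC"
  for (r in c("HC", "LC")) {
    n <- sum(role %in% r)
    if (n == 0) stop("missing ", r, " record in ", fasta_path, call. = FALSE)
    if (n > 1) stop("multiple ", r, " records in ", fasta_path, call. = FALSE)
  }
  cdrs <- NULL
  if (!is.null(regions_path)) {
    reg <- utils::read.delim(regions_path, stringsAsFactors = FALSE)
    need <- c("chain_id", "region_name", "start", "end")
    if (!all(need %in% names(reg))) {
      stop("regions file must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    cdrs <- data.frame(chain_id = reg$chain_id, name = reg$region_name,
                       start = reg$start, end = reg$end)
  }
  if (is.null(name)) name <- sub("\\|HC\\b.*$", "", hdr[role %in% "HC"])
  therapeutic_molecule(name,
                       hc = as.character(seqs[[which(role %in% "HC")]]),
                       lc = as.character(seqs[[which(role %in% "LC")]]),
                       cdrs = cdrs)
}

#' Write a therapeutic molecule back to FASTA + regions sidecar
#'
#' Inverse of [load_therapeutic()]; round-trips byte-identically for
#' molecules written by this function.
#'
#' @param mol a [therapeutic_molecule()]
#' @param fasta_path,regions_path output paths
#' @return invisibly, `fasta_path`
#' @export
write_therapeutic <- function(mol, fasta_path, regions_path) {
  seqs <- Biostrings::AAStringSet(c(mol$chains$HC, mol$chains$LC))
  names(seqs) <- paste0(mol$name, "|", c("HC", "LC"))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60L)
  reg <- data.frame(chain_id = mol$cdrs$chain_id, region_name = mol$cdrs$name,
                    start = mol$cdrs$start, end = mol$cdrs$end)
  write_tsv(reg, regions_path)
  invisible(fasta_path)
}

#' Ungapped percent identity between two equal-length sequence regions
#'
#' Positional identity over two equal-length intervals, as used when
#' comparing homologous framework/constant regions of two antibodies (for
#' instance a shared 26-residue framework cluster region differing at 4
#' positions). No alignment is performed; unequal interval lengths are an
#' error rather than an implicit gap placement. The result is
#' `100 * identical / length`, rounded half-up to the nearest integer —
#' the rounding convention is this package's own and is documented rather
#' than inferred.
#'
#' @param seq_a,seq_b amino-acid strings
#' @param interval_a,interval_b length-2 integer vectors `c(start, end)`,
#'   1-based inclusive, each valid on its sequence
#' @return integer percent identity in 0..100
#' @export
region_homology <- function(seq_a, seq_b, interval_a, interval_b) {
  check_aa(seq_a, "seq_a"); check_aa(seq_b, "seq_b")
  chk <- function(iv, s, nm) {
    if (length(iv) != 2L || iv[1] < 1L || iv[2] > nchar(s) || iv[1] > iv[2]) {
      stop("invalid interval for ", nm, call. = FALSE)
    }
  }
  chk(interval_a, seq_a, "seq_a"); chk(interval_b, seq_b, "seq_b")
  la <- interval_a[2] - interval_a[1] + 1L
  lb <- interval_b[2] - interval_b[1] + 1L
  if (la != lb) {
    stop("intervals have unequal lengths (", la, " vs ", lb,
         "); region_homology is ungapped", call. = FALSE)
  }
  a <- strsplit(substr(seq_a, interval_a[1], interval_a[2]), "")[[1]]
  b <- strsplit(substr(seq_b, interval_b[1], interval_b[2]), "")[[1]]
  as.integer(round_half_up(100 * sum(a == b) / la))
}
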
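# Identification-quality filtering: charge-dependent XCorr confidence tiers,
# modification-count cap, and concatenated target-decoy FDR.
#
# The q-value estimator here is the canonical minimal target-decoy analysis
# (TDA) and deliberately stands in for semi-supervised rescoring engines:
# the 1% FDR is treated as a contract, not an algorithm.

# XCorr tier constants by charge band. The medium band is a closed interval;
# "high" is strictly greater than its upper bound; below the medium floor is
# rejected. Charges 4-7 share one band.
XCORR_TIERS <- data.frame(
  band = c("2", "3", "4+"),
  medium_lo = c(2.0, 2.5, 2.8),
  medium_hi = c(2.3, 3.0, 3.5)
)

#' Confidence tier of a PSM from charge and XCorr (vectorized)
#'
#' Medium-confidence XCorr windows are 2-2.3, 2.5-3 and 2.8-3.5 for charge
#' 2, 3 and >= 4 (closed intervals); high confidence requires XCorr strictly
#' greater than 2.3, 3 and 3.5 respectively; anything below the medium floor
#' is rejected.
#'
#' @param charge integer vector in 2..7
#' @param xcorr non-negative numeric vector
#' @return ordered factor with levels reject < medium < high
#' @export
assign_confidence <- function(charge, xcorr) {
  if (any(is.na(charge) | charge < 2L | charge > 7L)) {
    stop("charge outside the accepted 2-7 range", call. = FALSE)
  }
  if (any(is.na(xcorr) | xcorr < 0)) {
    stop("xcorr must be non-negative", call. = FALSE)
  }
  band <- ifelse(charge >= 4L, 3L, charge - 1L)
  lo <- XCORR_TIERS$medium_lo[band]
  hi <- XCORR_TIERS$medium_hi[band]
  tier <- ifelse(xcorr > hi, "high", ifelse(xcorr >= lo, "medium", "reject"))
  factor(tier, levels = c("reject", "medium", "high"), ordered = TRUE)
}

#' Target-decoy q-values
#'
#' Records are scored against the concatenated target-decoy search model:
#' at each observed XCorr threshold `s`,
#' `FDR(s) = #(decoys with xcorr >= s) / max(1, #(targets with xcorr >= s))`
#' (the naive estimator, no +1 correction), and a record's q-value is the
#' minimum FDR over all thresholds at or below its score — i.e. the best
#' achievable FDR of an acceptance set that still contains the record.
#' q-values are therefore non-increasing in xcorr.
#'
#' @param records data.frame/data.table with `xcorr` and `is_decoy`
#' @return the input as a data.table with a `qvalue` column appended
#' @export
compute_qvalues <- function(records) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0) {
    dt[, qvalue := numeric(0)]
    return(dt[])
  }
  o <- order(-dt$xcorr)
  x <- dt$xcorr[o]
  d <- cumsum(dt$is_decoy[o])
  t <- cumsum(!dt$is_decoy[o])
  # collapse ties: counts at a threshold include every record scoring >= it,
  # so every member of a tie block uses the block's last cumulative count
  lens <- rle(x)$lengths
  idx <- rep(cumsum(lens), lens)
  fdr <- d[idx] / pmax(1L, t[idx])
  q <- rev(cummin(rev(fdr)))
  q <- pmin(q, 1)
  dt[o, qvalue := q]
  dt[]
}

#' Filtering configuration
#'
#' Defaults encode the study-level acceptance rules: peptide identifications
#' filtered to a 1% false discovery rate, at most four variable
#' modifications per peptide, and at least medium XCorr confidence.
#'
#' @param fdr_threshold peptide-level FDR (proportion, default 0.01)
#' @param max_mods maximum modifications per peptide (default 4)
#' @param tier_floor minimum confidence tier: "medium" or "high"
#' @return a `filter_config` list
#' @export
filter_config <- function(fdr_threshold = 0.01, max_mods = 4L,
                          tier_floor = "medium") {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1, max_mods >= 0,
            tier_floor %in% c("medium", "high"))
  structure(list(fdr_threshold = fdr_threshold,
                 max_mods = as.integer(max_mods),
                 tier_floor = tier_floor),
            class = "filter_config")
}

#' Apply the identification filters
#'
#' Keeps exactly the target records with `qvalue <= fdr_threshold`, tier at
#' or above the configured floor, and at most `max_mods` modifications.
#' Idempotent: re-filtering the output returns the same set. q-values and
#' tiers are computed on the fly when absent.
#'
#' @param records PSM data.table (per-sample q-value computation is the
#'   caller's choice; this function filters what it is given)
#' @param config a [filter_config()]
#' @return accepted records with `tier` and `qvalue` columns
#' @export
apply_filters <- function(records, config = filter_config()) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0) {
    if (!"tier" %in% names(dt)) dt[, tier := factor(character(),
      levels = c("reject", "medium", "high"), ordered = TRUE)]
    if (!"qvalue" %in% names(dt)) dt[, qvalue := numeric(0)]
    return(dt[])
  }
  if (!"qvalue" %in% names(dt)) dt <- compute_qvalues(dt)
  if (!"tier" %in% names(dt)) dt[, tier := assign_confidence(charge, xcorr)]
  floor_tier <- factor(config$tier_floor,
                       levels = c("reject", "medium", "high"), ordered = TRUE)
  keep <- !dt$is_decoy &
    dt$qvalue <= config$fdr_threshold &
    dt$tier >= floor_tier &
    count_mods(dt$mods) <= config$max_mods
  dt[keep][]
}
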
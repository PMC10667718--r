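# Donor-panel quantitative outputs: per-sample counts and percent
# therapeutic peptides, cluster presentation frequencies, biotransformation
# donor frequencies, length statistics and replicate concordance.

#' Percent therapeutic peptides of a sample
#'
#' `100 * (n_hc + n_lc) / n_total`, rounded half-up to 2 significant
#' figures, matching the convention of "mAb / total peptides (%)" summary
#' tables. The denominator is the count of distinct accepted peptide
#' sequences in the sample — therapeutic plus self-peptide background —
#' which is why observed values are small (totals run to tens of
#' thousands).
#'
#' @param n_hc,n_lc distinct accepted peptides mapping to the heavy / light
#'   chain
#' @param n_total distinct accepted peptides in the sample (> 0)
#' @return percent, 2 significant figures
#' @export
pct_therapeutic <- function(n_hc, n_lc, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  if (any(n_hc < 0 | n_lc < 0 | n_hc + n_lc > n_total)) {
    stop("need 0 <= n_hc + n_lc <= n_total", call. = FALSE)
  }
  signif_half_up(100 * (n_hc + n_lc) / n_total, 2)
}

#' Donor frequency of a biotransformation
#'
#' Percentage of panel donors with at least one accepted therapeutic
#' peptide bearing the modification kind (e.g. Met-ox seen in 8 of 18
#' donors gives 44), optionally restricted to a region on a chain, rounded
#' half-up to the nearest integer.
#'
#' @param mapped mapped-peptide table from [map_panel()]
#' @param panel_donor_count total donors in the panel (>= 1)
#' @param mod_kind "MetOx" or "Deamidation"
#' @param chain_id,region optional restriction: chain and `c(start, end)`
#'   interval the peptide placement must overlap
#' @return percent, nearest integer
#' @export
modification_donor_frequency <- function(mapped, panel_donor_count,
                                         mod_kind = c("MetOx",
                                                      "Deamidation"),
                                         chain_id = NULL, region = NULL) {
  mod_kind <- match.arg(mod_kind)
  if (panel_donor_count < 1) stop("empty panel", call. = FALSE)
  dt <- data.table::as.data.table(mapped)
  if (!is.null(chain_id)) dt <- dt[dt$chain_id == chain_id]
  if (!is.null(region)) {
    dt <- dt[interval_overlap(start, end, region[1], region[2]) >= 1L]
  }
  tag <- if (mod_kind == "MetOx") "(ox)" else "(deam)"
  hit <- grepl(tag, dt$mods, fixed = TRUE)
  n <- data.table::uniqueN(dt$donor_id[hit])
  as.integer(round_half_up(100 * n / panel_donor_count))
}

#' Cluster-level concordance between two runs
#'
#' Jaccard index of the two cluster sets under the cross-run matching of
#' [match_clusters_across_runs()], as a percentage rounded half-up to one
#' decimal: `100 * matched / (n_a + n_b - matched)`. Two empty runs agree
#' vacuously (100). Symmetric; equals 100 iff the matching is a perfect
#' matching of both sets.
#'
#' @param clusters_a,clusters_b cluster tables from [build_clusters()]
#' @param min_core_overlap core-overlap threshold for matching
#' @return percent with one decimal
#' @export
replicate_concordance <- function(clusters_a, clusters_b,
                                  min_core_overlap = 9L) {
  a <- data.table::as.data.table(clusters_a)
  b <- data.table::as.data.table(clusters_b)
  if (nrow(a) == 0 && nrow(b) == 0) return(100.0)
  m <- nrow(match_clusters_across_runs(a, b, min_core_overlap))
  round_half_up(100 * m / (nrow(a) + nrow(b) - m), 1)
}

#' Peptide-level concordance between two runs (secondary metric)
#'
#' Jaccard percentage of the distinct therapeutic peptide sequences of two
#' runs.
#'
#' @param mapped_a,mapped_b mapped-peptide tables
#' @return percent with one decimal
#' @export
peptide_concordance <- function(mapped_a, mapped_b) {
  pa <- unique(mapped_a$peptide); pb <- unique(mapped_b$peptide)
  if (length(pa) == 0 && length(pb) == 0) return(100.0)
  round_half_up(100 * length(intersect(pa, pb)) / length(union(pa, pb)), 1)
}

#' Per-sample summary rows
#'
#' One row per sample: distinct accepted peptides mapping to HC, to LC,
#' total distinct accepted peptides (therapeutic plus background), and
#' percent therapeutic. A peptide is counted once per chain it maps to;
#' peptide identity is the bare amino-acid sequence (modifications and
#' charge states ignored).
#'
#' @param accepted accepted PSM table (all peptides, incl. background)
#' @param mapped mapped-peptide table from [map_panel()]
#' @return data.table: sample_id, donor_id, n_hc_peptides, n_lc_peptides,
#'   n_total_peptides, pct_therapeutic
#' @export
sample_summaries <- function(accepted, mapped) {
  acc <- data.table::as.data.table(accepted)
  map <- data.table::as.data.table(mapped)
  tot <- acc[, list(donor_id = donor_id[1],
                    n_total_peptides = data.table::uniqueN(peptide)),
             by = sample_id]
  if (nrow(map)) {
    chain_counts <- map[, list(n = data.table::uniqueN(peptide)),
                        by = list(sample_id, chain_id)]
    wide <- data.table::dcast(chain_counts, sample_id ~ chain_id,
                              value.var = "n", fill = 0L)
    for (col in c("HC", "LC")) {
      if (!col %in% names(wide)) wide[, (col) := 0L]
    }
    out <- merge(tot, wide[, list(sample_id, n_hc_peptides = HC,
                                  n_lc_peptides = LC)],
                 by = "sample_id", all.x = TRUE)
  } else {
    out <- tot
    out[, c("n_hc_peptides", "n_lc_peptides") := list(0L, 0L)]
  }
  for (col in c("n_hc_peptides", "n_lc_peptides")) {
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, pct_therapeutic := pct_therapeutic(n_hc_peptides, n_lc_peptides,
                                           n_total_peptides)]
  data.table::setcolorder(out, c("sample_id", "donor_id", "n_hc_peptides",
                                 "n_lc_peptides", "n_total_peptides",
                                 "pct_therapeutic"))
  data.table::setorder(out, sample_id)
  out[]
}

#' Full panel report
#'
#' Aggregates the quantitative output surface of a donor panel:
#' per-sample summaries, the cluster table with donor presentation
#' frequencies, modification donor frequencies, length statistics, and the
#' pairwise cluster-concordance matrix across samples. Deterministic given
#' its inputs. When `out_dir` is given, writes `summary.json`,
#' `samples.tsv`, `clusters.tsv`, `frequencies.tsv` and `lengths.tsv`.
#'
#' @param accepted accepted PSM table
#' @param mapped mapped-peptide table
#' @param molecule the [therapeutic_molecule()]
#' @param min_core_overlap clustering/matching threshold
#' @param out_dir optional output directory
#' @return a `panel_summary` list
#' @export
panel_report <- function(accepted, mapped, molecule, min_core_overlap = 9L,
                         out_dir = NULL) {
  acc <- data.table::as.data.table(accepted)
  map <- data.table::as.data.table(mapped)
  donors <- sort(unique(acc$donor_id))
  n_donors <- length(donors)
  samples <- sample_summaries(acc, map)

  cl <- build_clusters(map, min_core_overlap)
  clusters <- cl$clusters
  if (nrow(clusters)) {
    clusters$frequency_pct <- cluster_presentation_frequency(
      clusters$n_donors, n_donors)
  } else {
    clusters$frequency_pct <- numeric(0)
  }

  freqs <- data.table::data.table(
    metric = c("MetOx", "Deamidation"),
    n_donors = c(
      sum(vapply(donors, function(d)
        any(grepl("(ox)", map$mods[map$donor_id == d], fixed = TRUE)),
        TRUE)),
      sum(vapply(donors, function(d)
        any(grepl("(deam)", map$mods[map$donor_id == d], fixed = TRUE)),
        TRUE))),
    panel_donors = n_donors)
  freqs$frequency_pct <- if (n_donors == 0) NA_integer_ else
    as.integer(round_half_up(100 * freqs$n_donors / n_donors))

  lens <- length_statistics(map)

  # pairwise cluster concordance across samples
  sample_ids <- sort(unique(acc$sample_id))
  per_sample_clusters <- lapply(sample_ids, function(sid) {
    build_clusters(map[map$sample_id == sid], min_core_overlap)$clusters
  })
  k <- length(sample_ids)
  conc <- matrix(100.0, k, k, dimnames = list(sample_ids, sample_ids))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        v <- replicate_concordance(per_sample_clusters[[i]],
                                   per_sample_clusters[[j]],
                                   min_core_overlap)
        conc[i, j] <- v; conc[j, i] <- v
      }
    }
  }

  res <- structure(list(
    molecule = molecule$name,
    n_donors = n_donors,
    samples = samples,
    clusters = clusters,
    mod_frequencies = freqs,
    length_stats = lens,
    concordance = conc), class = "panel_summary")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(samples, file.path(out_dir, "samples.tsv"))
    write_tsv(clusters, file.path(out_dir, "clusters.tsv"))
    write_tsv(freqs, file.path(out_dir, "frequencies.tsv"))
    write_tsv(lens$histogram, file.path(out_dir, "lengths.tsv"))
    json <- list(
      molecule = molecule$name,
      n_donors = n_donors,
      n_samples = nrow(samples),
      n_clusters = nrow(clusters),
      median_peptide_length = lens$median,
      samples = samples,
      clusters = clusters,
      mod_frequencies = freqs,
      mean_offdiag_concordance = if (k > 1)
        round_half_up(mean(conc[upper.tri(conc)]), 1) else NA)
    jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  res
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("<panel_summary> %s: %d donors, %d samples, %d clusters\n",
              x$molecule, x$n_donors, nrow(x$samples), nrow(x$clusters)))
  cat(sprintf("  median therapeutic peptide length: %s\n",
              x$length_stats$median))
  invisible(x)
}
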
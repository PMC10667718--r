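# Nested-set ("cluster") detection.
#
# Eluted MHC-II peptides around one binding core share a consensus sequence
# but have ragged N- and C-termini; such a group is a cluster (nested set).
# Grouping is greedy with core shrinking so that every cluster keeps a
# genuine common core — single-linkage can chain peptides with no shared
# core. min_core_overlap defaults to 9 residues, the canonical MHC class II
# binding-core length; the grouping threshold is a package convention, not
# a literature constant.

#' Build nested-set clusters from mapped peptides
#'
#' Per chain, distinct peptide intervals are sorted by start then by
#' decreasing length. The first unassigned interval seeds a cluster whose
#' core is that interval; each subsequent interval joins the first existing
#' cluster whose current core it overlaps by at least `min_core_overlap`
#' residues (shrinking the core to the intersection), otherwise it seeds a
#' new cluster. The procedure is deterministic given the sort order and
#' yields a partition: every mapped peptide belongs to exactly one cluster.
#' Clusters are numbered per molecule by (HC before LC, envelope start).
#'
#' @param mapped mapped-peptide table from [map_panel()] (needs `chain_id`,
#'   `start`, `end`; `donor_id`/`sample_id`/`peptide` used when present)
#' @param min_core_overlap minimum residue overlap with a cluster's current
#'   core for membership (default 9)
#' @return list with `clusters` (data.table: cluster_id, chain_id,
#'   core_start, core_end, envelope_start, envelope_end, n_peptides,
#'   n_donors) and `members` (the input plus a `cluster_id` column)
#' @export
build_clusters <- function(mapped, min_core_overlap = 9L) {
  stopifnot(min_core_overlap >= 1L)
  dt <- data.table::as.data.table(mapped)
  empty <- list(
    clusters = data.table::data.table(
      cluster_id = integer(), chain_id = character(), core_start = integer(),
      core_end = integer(), envelope_start = integer(),
      envelope_end = integer(), n_peptides = integer(), n_donors = integer()),
    members = cbind(dt, data.table::data.table(cluster_id = integer())))
  if (nrow(dt) == 0) return(empty)

  assign_chain <- function(iv) {
    # iv: data.table of distinct intervals, one chain
    o <- order(iv$start, -(iv$end - iv$start))
    iv <- iv[o]
    cs <- integer(0); ce <- integer(0)          # current cores
    es <- integer(0); ee <- integer(0)          # envelopes
    cl <- integer(nrow(iv))
    for (i in seq_len(nrow(iv))) {
      s <- iv$start[i]; e <- iv$end[i]
      hit <- 0L
      if (length(cs)) {
        ov <- interval_overlap(cs, ce, s, e)
        w <- which(ov >= min_core_overlap)
        if (length(w)) hit <- w[1]
      }
      if (hit == 0L) {
        cs <- c(cs, s); ce <- c(ce, e)
        es <- c(es, s); ee <- c(ee, e)
        cl[i] <- length(cs)
      } else {
        cs[hit] <- max(cs[hit], s); ce[hit] <- min(ce[hit], e)
        es[hit] <- min(es[hit], s); ee[hit] <- max(ee[hit], e)
        cl[i] <- hit
      }
    }
    iv[, cluster_local := cl]
    list(iv = iv,
         info = data.table::data.table(
           cluster_local = seq_along(cs), core_start = cs, core_end = ce,
           envelope_start = es, envelope_end = ee))
  }

  distinct <- unique(dt[, list(chain_id, start, end)])
  parts <- lapply(c("HC", "LC"), function(ch) {
    sub <- distinct[chain_id == ch]
    if (nrow(sub) == 0) return(NULL)
    res <- assign_chain(sub)
    res$info[, chain_id := ch]
    res$iv[, chain_id := ch]
    res
  })
  parts <- Filter(Negate(is.null), parts)
  info <- data.table::rbindlist(lapply(parts, `[[`, "info"), use.names = TRUE)
  ivmap <- data.table::rbindlist(lapply(parts, `[[`, "iv"), use.names = TRUE)

  # stable molecule-wide numbering: HC first, then envelope start
  data.table::setorder(info, chain_id, envelope_start, envelope_end)
  info[, cluster_id := seq_len(.N)]
  ivmap <- merge(ivmap, info[, list(chain_id, cluster_local, cluster_id)],
                 by = c("chain_id", "cluster_local"))
  members <- merge(dt, ivmap[, list(chain_id, start, end, cluster_id)],
                   by = c("chain_id", "start", "end"), sort = FALSE)

  stats <- members[, list(
    n_peptides = if ("peptide" %in% names(members))
      data.table::uniqueN(peptide) else .N,
    n_donors = if ("donor_id" %in% names(members))
      data.table::uniqueN(donor_id) else NA_integer_),
    by = cluster_id]
  clusters <- merge(info[, list(cluster_id, chain_id, core_start, core_end,
                                envelope_start, envelope_end)],
                    stats, by = "cluster_id", all.x = TRUE)
  data.table::setorder(clusters, cluster_id)
  list(clusters = clusters[], members = members[])
}

#' Donor presentation frequency of a cluster
#'
#' Percentage of panel donors whose cells presented at least one accepted
#' peptide of the cluster (presence/absence, no minimum peptide count),
#' rounded half-up to one decimal — e.g. 5 presenting donors of 7 gives
#' 71.4.
#'
#' @param n_presenting number of donors presenting the cluster
#' @param panel_donor_count total donors in the panel (>= 1)
#' @return percent with one decimal
#' @export
cluster_presentation_frequency <- function(n_presenting, panel_donor_count) {
  if (any(panel_donor_count < 1)) {
    stop("panel_donor_count must be >= 1", call. = FALSE)
  }
  if (any(n_presenting > panel_donor_count)) {
    stop("more presenting donors than panel donors", call. = FALSE)
  }
  round_half_up(100 * n_presenting / panel_donor_count, 1)
}

#' Match clusters across two runs of the same molecule
#'
#' Two clusters are matchable iff they lie on the same chain and their
#' cores overlap by at least `min_core_overlap` residues. Pairing is greedy
#' one-to-one by descending core overlap (ties broken by cluster_id pairs),
#' which is what makes "the same cluster was found in both runs" a
#' well-defined statement for concordance metrics.
#'
#' @param clusters_a,clusters_b cluster tables from [build_clusters()]
#' @param min_core_overlap minimum core overlap (default 9)
#' @return data.table with columns `cluster_id_a`, `cluster_id_b`, `overlap`
#' @export
match_clusters_across_runs <- function(clusters_a, clusters_b,
                                       min_core_overlap = 9L) {
  a <- data.table::as.data.table(clusters_a)
  b <- data.table::as.data.table(clusters_b)
  out <- data.table::data.table(cluster_id_a = integer(),
                                cluster_id_b = integer(),
                                overlap = integer())
  if (nrow(a) == 0 || nrow(b) == 0) return(out)
  cand <- data.table::CJ(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
  cand[, overlap := {
    same <- a$chain_id[ia] == b$chain_id[ib]
    ov <- interval_overlap(a$core_start[ia], a$core_end[ia],
                           b$core_start[ib], b$core_end[ib])
    ifelse(same, ov, 0L)
  }]
  cand <- cand[overlap >= min_core_overlap]
  data.table::setorder(cand, -overlap, ia, ib)
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  for (i in seq_len(nrow(cand))) {
    ia <- cand$ia[i]; ib <- cand$ib[i]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      out <- rbind(out, data.table::data.table(
        cluster_id_a = a$cluster_id[ia], cluster_id_b = b$cluster_id[ib],
        overlap = cand$overlap[i]))
    }
  }
  out[]
}
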
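# data.table non-standard-evaluation columns
utils::globalVariables(c(
  "qvalue", "tier", "peptide", "cdrs", "chain_id", "start", "end",
  "unique_to_therapeutic", "mods", "mods_chain", "cluster_id",
  "cluster_local", "envelope_start", "envelope_end", "core_start",
  "core_end", "n_peptides", "n_donors", "donor_id", "sample_id",
  "frequency_pct", "panel_donors", "overlap", "ia", "ib", "HC", "LC",
  "n_hc_peptides", "n_lc_peptides", "n_total_peptides", "core_id",
  "presented", "replicate", "day", "analyst", "n", "metric",
  "pct_therapeutic"))

#' @importFrom data.table := .N .SD
#' @importFrom stats rpois rgeom runif rlnorm rnbinom
NULL
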
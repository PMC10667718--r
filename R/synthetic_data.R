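# Synthetic MAPPs panels with ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes, so that every stage is testable without raw mass-spectrometry
# data: nested sets with ragged N/C termini around planted 9-mer binding
# cores; a peptide length distribution with median 16 (range 13-25);
# donor-specific presentation (a donor misses a core with probability
# 1 - donor_presentation_prob, emulating the ~30% donor variability seen in
# real panels); replicate/day/analyst structure with peptide dropout;
# large self-peptide backgrounds (totals in the 1e4-3e4 range seen in
# panel summary tables); reversed-sequence decoys and low-scoring false
# target matches for target-decoy FDR; charges 2-7; and Met-ox / N-Q
# deamidation injection with localized/unlocalized status.
#
# XCorr model: a true PSM scores medium_floor(charge) + LogNormal(log 0.5,
# sigma 0.8), so true identifications are never tier-rejected and both the
# medium and the high tier are populated; decoys and false targets score
# LogNormal(log 1.1, sigma 0.35). These distributions are a modeling
# convenience (they make replicate variation come only from dropout), not a
# claim about any search engine.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste0(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
  }, "")
}

#' Simulation configuration
#'
#' Defaults state the emulated world once: 7-donor panels, 9-mer cores with
#' presentation probability 0.7 per (donor, core), Poisson(5)-sized peptide
#' ladders (minimum 1), ragged terminal extensions of 2 + Geometric(0.35)
#' residues per side capped at total length 25 (distributional median
#' length 16, support 13-25), self-peptide backgrounds of 1e4-3e4 distinct
#' sequences per sample, and per-peptide replicate dropout 0.02.
#'
#' @param seed integer seed fixing every random draw
#' @param n_donors donors in the panel
#' @param n_replicates_per_donor technical replicates per donor
#' @param n_cores_hc,n_cores_lc planted binding cores per chain
#' @param core_positions optional data.frame (chain_id, start) overriding
#'   random placement; cores are 9 residues, pairwise separated by > 25
#'   residues and >= 20 residues from the chain ends
#' @param donor_presentation_prob Bernoulli presentation probability per
#'   (donor, core); scalar or one value per core
#' @param ladder_mean Poisson mean of peptides per presented core per
#'   sample (floored at 1)
#' @param ext_geom_p geometric parameter of the ragged terminal extensions
#' @param max_peptide_len total length cap (trimming the longer extension)
#' @param background_range range of background peptides per sample
#'   (one count drawn uniformly per sample)
#' @param false_match_rate false-spectrum count as a fraction of the
#'   background count; each false spectrum lands on the decoy half of the
#'   concatenated database with probability `decoy_split`
#' @param decoy_split probability a false spectrum matches a decoy
#' @param charge_probs named probabilities over charges 2-7
#' @param metox_prob per-M oxidation injection probability
#' @param deamidation_prob per-N/Q deamidation injection probability
#' @param unlocalized_fraction fraction of injected deamidations left
#'   unlocalized
#' @param replicate_dropout_prob per-peptide dropout probability per
#'   replicate
#' @param hc_len,lc_len chain lengths
#' @param n_background_proteins,background_protein_len background proteome
#'   shape
#' @param molecule_name name of the synthetic molecule
#' @return a `simulation_config` list
#' @export
simulation_config <- function(seed = 1L,
                              n_donors = 7L,
                              n_replicates_per_donor = 1L,
                              n_cores_hc = 3L,
                              n_cores_lc = 2L,
                              core_positions = NULL,
                              donor_presentation_prob = 0.7,
                              ladder_mean = 5,
                              ext_geom_p = 0.35,
                              max_peptide_len = 25L,
                              background_range = c(10000L, 30000L),
                              false_match_rate = 0.25,
                              decoy_split = 0.5,
                              charge_probs = c("2" = 0.45, "3" = 0.35,
                                               "4" = 0.12, "5" = 0.05,
                                               "6" = 0.02, "7" = 0.01),
                              metox_prob = 0.15,
                              deamidation_prob = 0.10,
                              unlocalized_fraction = 0.3,
                              replicate_dropout_prob = 0.02,
                              hc_len = 450L,
                              lc_len = 214L,
                              n_background_proteins = 50L,
                              background_protein_len = 400L,
                              molecule_name = "synthmab1") {
  cfg <- as.list(environment())
  probs <- c(donor_presentation_prob, metox_prob, deamidation_prob,
             unlocalized_fraction, replicate_dropout_prob, decoy_split,
             ext_geom_p)
  stopifnot(all(probs >= 0 & probs <= 1),
            n_donors >= 1, n_replicates_per_donor >= 1,
            ladder_mean > 0, max_peptide_len >= 13,
            abs(sum(charge_probs) - 1) < 1e-8,
            identical(names(charge_probs), as.character(2:7)))
  structure(cfg, class = "simulation_config")
}

# place k 9-mer cores on a chain of length len: >= margin from the ends and
# pairwise gaps > 25 residues
place_cores <- function(k, len, margin = 20L, gap = 25L, core_len = 9L) {
  if (k == 0) return(integer(0))
  lo <- margin + 1L
  hi <- len - margin - core_len + 1L
  need <- k * core_len + (k - 1L) * (gap + 1L)
  if (hi - lo + 1L < need) stop("chain too short for ", k, " cores",
                                call. = FALSE)
  repeat {
    st <- sort(sample(lo:hi, k))
    if (k == 1 || all(diff(st) > core_len + gap)) return(st)
  }
}

draw_charges <- function(n, probs) {
  as.integer(sample(names(probs), n, replace = TRUE, prob = probs))
}

true_xcorr <- function(charge) {
  band <- ifelse(charge >= 4L, 3L, charge - 1L)
  XCORR_TIERS$medium_lo[band] + stats::rlnorm(length(charge), log(0.5), 0.8)
}

null_xcorr <- function(n) stats::rlnorm(n, log(1.1), 0.35)

# inject Met-ox / N-Q deamidation into peptides; returns mods strings.
# At most 4 tokens are injected (the search-engine cap downstream).
inject_mods <- function(peptides, metox_prob, deamidation_prob,
                        unlocalized_fraction) {
  vapply(peptides, function(p) {
    res <- strsplit(p, "")[[1]]
    toks <- character(0)
    mpos <- which(res == "M")
    mpos <- mpos[stats::runif(length(mpos)) < metox_prob]
    if (length(mpos)) toks <- c(toks, paste0("M", mpos, "(ox)"))
    dpos <- which(res %in% c("N", "Q"))
    dpos <- dpos[stats::runif(length(dpos)) < deamidation_prob]
    if (length(dpos)) {
      unloc <- stats::runif(length(dpos)) < unlocalized_fraction
      toks <- c(toks, paste0(res[dpos], ifelse(unloc, "?", dpos), "(deam)"))
    }
    if (length(toks) > 4L) toks <- toks[1:4]
    paste(toks, collapse = ";")
  }, "", USE.NAMES = FALSE)
}

#' Simulate a MAPPs donor panel with ground truth
#'
#' Deterministic given `config$seed`. Returns everything in memory; when
#' `out_dir` is given, additionally writes the exact file formats the
#' pipeline consumes (therapeutic FASTA + regions sidecar, background
#' FASTA, one PSM TSV per sample) plus truth tables as TSV.
#'
#' @param config a [simulation_config()]
#' @param out_dir optional output directory
#' @return list with `molecule`, `background` (AAStringSet), `samples`
#'   (sample_id, donor_id, day, analyst), `psm` (all samples, PSM column
#'   set), and `truth` (list: `cores`, `presentation`, `peptides` —
#'   emitted true therapeutic peptides post-dropout — and `true_peptides`,
#'   the per-sample set of correct target identifications incl.
#'   background)
#' @export
simulate_panel <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  res <- with_seed(config$seed, simulate_panel_impl(config))
  if (!is.null(out_dir)) write_panel(res, out_dir)
  res
}

simulate_panel_impl <- function(cfg) {
  # --- therapeutic molecule ------------------------------------------------
  hc <- random_aa(1, cfg$hc_len)
  lc <- random_aa(1, cfg$lc_len)
  cdrs <- data.frame(
    chain_id = c("HC", "HC", "HC", "LC", "LC", "LC"),
    name = c("HC CDR1", "HC CDR2", "HC CDR3",
             "LC CDR1", "LC CDR2", "LC CDR3"),
    start = c(26L, 50L, 99L, 24L, 50L, 89L),
    end = c(35L, 66L, 108L, 34L, 56L, 97L))
  mol <- therapeutic_molecule(cfg$molecule_name, hc, lc, cdrs)

  if (is.null(cfg$core_positions)) {
    cores <- data.table::data.table(
      chain_id = c(rep("HC", cfg$n_cores_hc), rep("LC", cfg$n_cores_lc)),
      start = c(place_cores(cfg$n_cores_hc, cfg$hc_len),
                place_cores(cfg$n_cores_lc, cfg$lc_len)))
  } else {
    cores <- data.table::as.data.table(cfg$core_positions)
  }
  cores[, end := start + 8L]
  cores[, core_id := seq_len(.N)]
  n_cores <- nrow(cores)
  pres_prob <- rep(cfg$donor_presentation_prob, length.out = n_cores)

  # --- background proteome -------------------------------------------------
  bg_seqs <- random_aa(cfg$n_background_proteins, cfg$background_protein_len)
  bg_acc <- sprintf("BGP%03d", seq_along(bg_seqs))
  background <- Biostrings::AAStringSet(bg_seqs)
  names(background) <- bg_acc
  chains_cat <- paste(hc, lc, sep = "-")   # "-" never occurs in a peptide

  # --- panel structure -----------------------------------------------------
  donors <- sprintf("D%02d", seq_len(cfg$n_donors))
  samples <- data.table::CJ(donor_id = donors,
                            replicate = seq_len(cfg$n_replicates_per_donor),
                            sorted = TRUE)
  samples[, sample_id := sprintf("%s_R%02d", donor_id, replicate)]
  samples[, day := sprintf("day%d", ((replicate - 1L) %% 3L) + 1L)]
  samples[, analyst := c("A", "B")[((replicate - 1L) %/% 3L) %% 2L + 1L]]

  presentation <- data.table::CJ(donor_id = donors,
                                 core_id = cores$core_id, sorted = TRUE)
  presentation[, presented := stats::runif(.N) < pres_prob[core_id]]

  ext_draw <- function(n) 2L + stats::rgeom(n, cfg$ext_geom_p)

  psm_list <- vector("list", nrow(samples))
  truth_pep_list <- vector("list", nrow(samples))
  true_pep_list <- vector("list", nrow(samples))

  for (si in seq_len(nrow(samples))) {
    srow <- samples[si]
    pres <- presentation[donor_id == srow$donor_id & presented == TRUE]
    # -- therapeutic ladders
    ther <- NULL
    if (nrow(pres)) {
      nlad <- pmax(1L, stats::rpois(nrow(pres), cfg$ladder_mean))
      core_idx <- rep(match(pres$core_id, cores$core_id), nlad)
      n_t <- length(core_idx)
      nex <- ext_draw(n_t); cex <- ext_draw(n_t)
      # cap total length by trimming extensions (never below 2 per side);
      # always feasible since 9 + 2 + 2 = 13 <= max_peptide_len
      over <- pmax(0L, 9L + nex + cex - cfg$max_peptide_len)
      t_n <- pmin(over, nex - 2L)
      t_c <- over - t_n
      nex <- nex - t_n; cex <- cex - t_c
      ch <- cores$chain_id[core_idx]
      cs <- cores$start[core_idx]; ce <- cores$end[core_idx]
      chlen <- ifelse(ch == "HC", cfg$hc_len, cfg$lc_len)
      ps <- pmax(1L, cs - nex); pe <- pmin(chlen, ce + cex)
      seqs <- ifelse(ch == "HC", hc, lc)
      pep <- substr(seqs, ps, pe)
      keep <- stats::runif(n_t) >= cfg$replicate_dropout_prob
      if (any(keep)) {
        ther <- data.table::data.table(
          peptide = pep[keep], core_id = cores$core_id[core_idx][keep],
          chain_id = ch[keep])
      }
    }
    n_ther <- if (is.null(ther)) 0L else nrow(ther)

    # -- background self peptides
    n_bg <- sample(cfg$background_range[1]:cfg$background_range[2], 1L)
    pidx <- sample.int(length(bg_seqs), n_bg, replace = TRUE)
    blen <- pmin(13L + stats::rnbinom(n_bg, 2, cfg$ext_geom_p),
                 cfg$max_peptide_len)
    bstart <- 1L + floor(stats::runif(n_bg) *
                           (cfg$background_protein_len - blen + 1L))
    bpep <- substr(bg_seqs[pidx], bstart, bstart + blen - 1L)
    clash <- vapply(bpep, function(p) grepl(p, chains_cat, fixed = TRUE),
                    TRUE, USE.NAMES = FALSE)
    while (any(clash)) {   # essentially never triggers for random chains
      n_r <- sum(clash)
      pidx[clash] <- sample.int(length(bg_seqs), n_r, replace = TRUE)
      bstart[clash] <- 1L + floor(stats::runif(n_r) *
                                    (cfg$background_protein_len -
                                       blen[clash] + 1L))
      bpep[clash] <- substr(bg_seqs[pidx[clash]], bstart[clash],
                            bstart[clash] + blen[clash] - 1L)
      clash <- vapply(bpep, function(p) grepl(p, chains_cat, fixed = TRUE),
                      TRUE, USE.NAMES = FALSE)
    }

    # -- false spectra: reversed background-like sequences
    n_false <- round(cfg$false_match_rate * n_bg)
    fidx <- sample.int(length(bg_seqs), n_false, replace = TRUE)
    flen <- pmin(13L + stats::rnbinom(n_false, 2, cfg$ext_geom_p),
                 cfg$max_peptide_len)
    fstart <- 1L + floor(stats::runif(n_false) *
                           (cfg$background_protein_len - flen + 1L))
    fpep <- vapply(strsplit(substr(bg_seqs[fidx], fstart,
                                   fstart + flen - 1L), ""),
                   function(x) paste(rev(x), collapse = ""), "")
    f_is_decoy <- stats::runif(n_false) < cfg$decoy_split

    # -- assemble the sample's PSM rows
    n_true <- n_ther + n_bg
    true_pep <- c(if (n_ther) ther$peptide, bpep)
    charge_true <- draw_charges(n_true, cfg$charge_probs)
    charge_false <- draw_charges(n_false, cfg$charge_probs)
    mods_ther <- if (n_ther) {
      inject_mods(ther$peptide, cfg$metox_prob, cfg$deamidation_prob,
                  cfg$unlocalized_fraction)
    } else character(0)
    psm <- data.table::data.table(
      sample_id = srow$sample_id, donor_id = srow$donor_id,
      day = srow$day, analyst = srow$analyst,
      peptide = c(true_pep, fpep),
      charge = c(charge_true, charge_false),
      xcorr = round(c(true_xcorr(charge_true), null_xcorr(n_false)), 4),
      mods = c(mods_ther, rep("", n_bg + n_false)),
      proteins = c(rep(cfg$molecule_name, n_ther), bg_acc[pidx],
                   ifelse(f_is_decoy, paste0("DECOY_", bg_acc[fidx]),
                          bg_acc[fidx])),
      is_decoy = c(rep(FALSE, n_true), f_is_decoy))
    psm_list[[si]] <- psm
    if (n_ther) {
      truth_pep_list[[si]] <- data.table::data.table(
        sample_id = srow$sample_id, donor_id = srow$donor_id, ther)
    }
    true_pep_list[[si]] <- data.table::data.table(
      sample_id = srow$sample_id, peptide = unique(true_pep))
  }

  list(
    molecule = mol,
    background = background,
    samples = samples[, list(sample_id, donor_id, day, analyst)],
    psm = data.table::rbindlist(psm_list),
    truth = list(
      cores = cores[, list(core_id, chain_id, start, end)],
      presentation = presentation,
      peptides = data.table::rbindlist(c(list(data.table::data.table(
        sample_id = character(), donor_id = character(),
        peptide = character(), core_id = integer(),
        chain_id = character())), truth_pep_list)),
      true_peptides = data.table::rbindlist(true_pep_list)))
}

write_panel <- function(panel, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_therapeutic(panel$molecule,
                    file.path(out_dir, "therapeutic.fasta"),
                    file.path(out_dir, "regions.tsv"))
  Biostrings::writeXStringSet(panel$background,
                              file.path(out_dir, "background.fasta"),
                              width = 60L)
  for (sid in panel$samples$sample_id) {
    write_psm_table(panel$psm[panel$psm$sample_id == sid],
                    file.path(out_dir, paste0("psm_", sid, ".tsv")))
  }
  write_tsv(panel$truth$cores, file.path(out_dir, "truth_cores.tsv"))
  write_tsv(panel$truth$presentation,
            file.path(out_dir, "truth_presentation.tsv"))
  write_tsv(panel$truth$peptides, file.path(out_dir, "truth_peptides.tsv"))
  write_tsv(panel$truth$true_peptides,
            file.path(out_dir, "truth_true_peptides.tsv"))
  invisible(out_dir)
}

#' Compare pipeline output against simulation ground truth
#'
#' Reports the recovery metrics that make synthetic panels informative:
#' realized false-discovery proportion among accepted target PSMs (a PSM is
#' false when its (sample, peptide) pair is not in the generator's true-
#' identification set), peptide-level sensitivity over the emitted true
#' therapeutic peptides, planted-core cluster recovery (recovered cores /
#' presented cores, per donor, pooled), and per-donor cluster counts.
#'
#' @param accepted accepted PSM table from [apply_filters()]
#' @param truth the `truth` element of [simulate_panel()] output
#' @param molecule the panel's [therapeutic_molecule()]
#' @param min_core_overlap clustering threshold
#' @return list: `realized_fdr`, `peptide_sensitivity`, `cluster_recovery`,
#'   `donor_cluster_counts` (data.table), `donor_clusters` (list)
#' @export
truth_compare <- function(accepted, truth, molecule, min_core_overlap = 9L) {
  acc <- data.table::as.data.table(accepted)
  if (!"tier" %in% names(acc)) acc[, tier := assign_confidence(charge, xcorr)]
  tp <- truth$true_peptides
  key <- paste(acc$sample_id, acc$peptide)
  truekey <- paste(tp$sample_id, tp$peptide)
  n_acc <- nrow(acc)
  realized_fdr <- if (n_acc == 0) 0 else mean(!(key %in% truekey))

  emitted <- unique(truth$peptides[, list(sample_id, peptide)])
  if (nrow(emitted)) {
    ekey <- paste(emitted$sample_id, emitted$peptide)
    sens <- mean(ekey %in% key)
  } else {
    sens <- NA_real_
  }

  mapped <- map_panel(acc, molecule)
  donors <- sort(unique(truth$presentation$donor_id))
  recovered <- 0L; presented_total <- 0L
  counts <- vector("list", length(donors))
  cl_list <- list()
  for (i in seq_along(donors)) {
    d <- donors[i]
    cl <- build_clusters(mapped[mapped$donor_id == d], min_core_overlap)
    cl_list[[d]] <- cl$clusters
    pres <- truth$presentation[donor_id == d & presented == TRUE]
    pcores <- truth$cores[truth$cores$core_id %in% pres$core_id]
    presented_total <- presented_total + nrow(pcores)
    if (nrow(pcores) && nrow(cl$clusters)) {
      for (j in seq_len(nrow(pcores))) {
        same <- cl$clusters[chain_id == pcores$chain_id[j]]
        ov <- interval_overlap(same$core_start, same$core_end,
                               pcores$start[j], pcores$end[j])
        if (any(ov >= 9L)) recovered <- recovered + 1L
      }
    }
    counts[[i]] <- data.table::data.table(donor_id = d,
                                          n_clusters = nrow(cl$clusters))
  }
  list(realized_fdr = realized_fdr,
       peptide_sensitivity = sens,
       cluster_recovery = if (presented_total == 0) NA_real_
                          else recovered / presented_total,
       donor_cluster_counts = data.table::rbindlist(counts),
       donor_clusters = cl_list)
}
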
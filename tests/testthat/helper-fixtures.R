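# Fixtures are built in code; nothing binary ships with the package.

# Deterministic "random" chain built from a fixed seed, so tests can state
# exact coordinates against it.
fixture_chain <- function(len, seed) {
  withr::with_seed(seed, paste0(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
    collapse = ""))
}

# A small molecule with hand-placed CDRs: HC 120 aa, LC 107 aa, 3 CDRs each.
make_molecule <- function() {
  therapeutic_molecule(
    name = "testmab",
    hc = fixture_chain(120, 101),
    lc = fixture_chain(107, 102),
    cdrs = data.frame(
      chain_id = c("HC", "HC", "HC", "LC", "LC", "LC"),
      name = c("HC CDR1", "HC CDR2", "HC CDR3",
               "LC CDR1", "LC CDR2", "LC CDR3"),
      start = c(26L, 50L, 97L, 24L, 50L, 89L),
      end = c(35L, 66L, 110L, 34L, 56L, 97L)))
}

write_molecule_fixture <- function(mol = make_molecule(),
                                   dir = withr::local_tempdir(.local_envir =
                                     parent.frame())) {
  fa <- file.path(dir, "therapeutic.fasta")
  reg <- file.path(dir, "regions.tsv")
  write_therapeutic(mol, fa, reg)
  list(fasta = fa, regions = reg, mol = mol)
}

# One valid PSM row; override fields as needed.
make_psm <- function(...) {
  row <- list(sample_id = "S1", donor_id = "D01", day = "day1",
              analyst = "A", peptide = "ACDEFGHIKL", charge = 2L,
              xcorr = 3.1, mods = "", proteins = "P1", is_decoy = FALSE)
  over <- list(...)
  row[names(over)] <- over
  data.table::as.data.table(row)
}

# Small, fast simulation config for plumbing tests (background scaled down;
# the full-scale defaults are exercised in test-acceptance.R).
small_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, n_donors = 3L,
                    background_range = c(400L, 500L), ...)
}

# Brute-force q-value oracle: at each observed threshold s,
# FDR(s) = D(>=s) / max(1, T(>=s)); q(record) = min over thresholds <= its
# score. Independent of the implementation's sort/cummin path.
qvalue_oracle <- function(xcorr, is_decoy) {
  thr <- sort(unique(xcorr))
  fdr <- vapply(thr, function(s) {
    sum(is_decoy[xcorr >= s]) / max(1, sum(!is_decoy[xcorr >= s]))
  }, 1.0)
  vapply(xcorr, function(x) min(1, fdr[thr <= x]), 1.0)
}

# Brute-force clustering oracle: connected components of the graph whose
# edges are interval pairs overlapping by >= min_ov.
component_oracle <- function(start, end, min_ov) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          min(end[i], end[j]) - max(start[i], start[j]) + 1 >= min_ov) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}
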
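test_that("simulation is deterministic given the seed", {
  p1 <- simulate_panel(small_config(seed = 9))
  p2 <- simulate_panel(small_config(seed = 9))
  expect_identical(p1$psm, p2$psm)
  expect_identical(p1$molecule$chains, p2$molecule$chains)
  expect_identical(p1$truth$cores, p2$truth$cores)
  p3 <- simulate_panel(small_config(seed = 10))
  expect_false(identical(p1$psm$peptide, p3$psm$peptide))
})

test_that("written panels are valid pipeline inputs", {
  d <- withr::local_tempdir()
  panel <- simulate_panel(small_config(seed = 12), out_dir = d)
  mol <- load_therapeutic(file.path(d, "therapeutic.fasta"),
                          file.path(d, "regions.tsv"))
  expect_identical(mol$chains, panel$molecule$chains)
  f <- list.files(d, pattern = "^psm_.*\\.tsv$", full.names = TRUE)
  expect_length(f, 3L)
  back <- read_psm_table(f[1])
  expect_equal(as.data.frame(back),
               as.data.frame(panel$psm[sample_id == back$sample_id[1]]))
})

test_that("presentation probability zero yields no therapeutic peptides", {
  panel <- simulate_panel(small_config(seed = 13,
                                       donor_presentation_prob = 0))
  expect_equal(nrow(panel$truth$peptides), 0L)
  expect_false(any(panel$psm$proteins == "synthmab1"))
})

test_that("true peptides contain their planted 9-mer core", {
  panel <- simulate_panel(small_config(seed = 14))
  tp <- panel$truth$peptides
  expect_gt(nrow(tp), 0L)
  cores <- panel$truth$cores
  core_seq <- vapply(seq_len(nrow(cores)), function(i) {
    substr(panel$molecule$chains[[cores$chain_id[i]]],
           cores$start[i], cores$end[i])
  }, "")
  expect_true(all(mapply(function(pep, cid) {
    grepl(core_seq[cid], pep, fixed = TRUE)
  }, tp$peptide, tp$core_id)))
  expect_true(all(nchar(tp$peptide) >= 13 & nchar(tp$peptide) <= 25))
})

test_that("background peptides never substring-match the chains", {
  panel <- simulate_panel(small_config(seed = 15))
  bg <- panel$psm[!panel$psm$is_decoy &
                    panel$psm$proteins != "synthmab1", peptide]
  chains <- paste(panel$molecule$chains$HC, panel$molecule$chains$LC,
                  sep = "-")
  expect_false(any(vapply(unique(bg), function(p)
    grepl(p, chains, fixed = TRUE), TRUE)))
})

test_that("presenting-donor fraction tracks the presentation probability", {
  # binomial expectation: mean presenting fraction per core ~ 0.7
  fracs <- vapply(1:50, function(s) {
    panel <- simulate_panel(simulation_config(
      seed = s, n_donors = 7, background_range = c(50L, 60L),
      donor_presentation_prob = 0.7))
    mean(panel$truth$presentation$presented)
  }, 1.0)
  expect_lt(abs(mean(fracs) - 0.7), 0.1)
})

test_that("truth_compare recovers a separable configuration exactly", {
  cfg <- simulation_config(seed = 21, n_donors = 3,
                           n_cores_hc = 3L, n_cores_lc = 0L,
                           donor_presentation_prob = 1,
                           replicate_dropout_prob = 0,
                           background_range = c(2000L, 2500L))
  panel <- simulate_panel(cfg)
  acc <- data.table::rbindlist(lapply(split(panel$psm, by = "sample_id"),
                                      apply_filters))
  tc <- truth_compare(acc, panel$truth, panel$molecule)
  expect_equal(tc$cluster_recovery, 1.0)
  expect_equal(tc$donor_cluster_counts$n_clusters, rep(3L, 3))
  expect_equal(tc$peptide_sensitivity, 1.0)
  expect_lte(tc$realized_fdr, 0.02)
})

test_that("never-presented cores are excluded from the recovery denominator", {
  cfg <- simulation_config(seed = 22, n_donors = 3,
                           n_cores_hc = 3L, n_cores_lc = 0L,
                           donor_presentation_prob = c(1, 1, 0),
                           replicate_dropout_prob = 0,
                           background_range = c(2000L, 2500L))
  panel <- simulate_panel(cfg)
  pres <- panel$truth$presentation
  expect_true(all(pres$presented[pres$core_id %in% 1:2]))
  expect_false(any(pres$presented[pres$core_id == 3]))
  acc <- data.table::rbindlist(lapply(split(panel$psm, by = "sample_id"),
                                      apply_filters))
  tc <- truth_compare(acc, panel$truth, panel$molecule)
  expect_equal(tc$cluster_recovery, 1.0)
  expect_equal(tc$donor_cluster_counts$n_clusters, rep(2L, 3))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(donor_presentation_prob = 1.4))
  expect_error(simulation_config(charge_probs = c("2" = 1)))
  expect_error(simulate_panel(list(seed = 1)), "simulation_config")
})
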
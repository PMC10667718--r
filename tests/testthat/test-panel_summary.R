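# minimal mapped-peptide rows for summary metrics
mapped_row <- function(donor, mods = "", chain = "HC", s = 50L, e = 65L,
                       pep = NULL) {
  data.table::data.table(
    sample_id = paste0(donor, "_R01"), donor_id = donor, day = "day1",
    analyst = "A", peptide = pep %||% strrep("A", e - s + 1L), charge = 2L,
    xcorr = 3, mods = mods, tier = "high", chain_id = chain,
    start = s, end = e, cdrs = "", unique_to_therapeutic = TRUE,
    mods_chain = mods)
}

test_that("pct_therapeutic reproduces the worked percentages", {
  expect_equal(pct_therapeutic(8, 3, 12416), 0.089)
  expect_equal(pct_therapeutic(12, 8, 29428), 0.068)
  expect_equal(pct_therapeutic(0, 0, 1000), 0)
  expect_error(pct_therapeutic(1, 0, 0), "positive")
  expect_error(pct_therapeutic(5, 6, 10), "n_total")
})

test_that("pct_therapeutic is monotone before rounding", {
  withr::with_seed(5, {
    for (i in 1:50) {
      tot <- sample(1000:30000, 1)
      h <- sample(0:20, 1); l <- sample(0:20, 1)
      raw <- function(h, l) 100 * (h + l) / tot
      expect_gte(raw(h + 1, l), raw(h, l))
      expect_gte(pct_therapeutic(h + 1, l, tot) -
                   pct_therapeutic(h, l, tot), -1e-9)
    }
  })
})

test_that("modification donor frequency counts donors, not peptides", {
  donors <- sprintf("D%02d", 1:18)
  rows <- lapply(donors, function(d) {
    mapped_row(d, mods = if (d %in% sprintf("D%02d", 1:8)) "M52(ox)" else "")
  })
  # a donor with many modified peptides still counts once
  rows <- c(rows, list(mapped_row("D01", mods = "M52(ox)")))
  mp <- data.table::rbindlist(rows)
  expect_equal(modification_donor_frequency(mp, 18, "MetOx"), 44L)
  expect_equal(modification_donor_frequency(mp, 18, "Deamidation"), 0L)

  # 2 of 5 donors with deamidation -> 40
  mp5 <- data.table::rbindlist(lapply(sprintf("D%02d", 1:5), function(d) {
    mapped_row(d, mods = if (d %in% c("D01", "D02")) "N?(deam)" else "")
  }))
  expect_equal(modification_donor_frequency(mp5, 5, "Deamidation"), 40L)

  # region restriction: mods outside the window do not count
  expect_equal(modification_donor_frequency(mp, 18, "MetOx",
                                            chain_id = "HC",
                                            region = c(100L, 120L)), 0L)
  expect_error(modification_donor_frequency(mp, 0, "MetOx"), "empty")
})

test_that("replicate concordance is cluster-level Jaccard", {
  a <- build_clusters(data.table::data.table(
    chain_id = "HC", start = c(10L, 40L), end = c(25L, 55L)))$clusters
  expect_equal(replicate_concordance(a, a), 100.0)
  b <- build_clusters(data.table::data.table(
    chain_id = "HC", start = c(100L), end = c(115L)))$clusters
  expect_equal(replicate_concordance(a, b), 0.0)
  # 2 matched, 3 total distinct -> 66.7
  ab <- build_clusters(data.table::data.table(
    chain_id = "HC", start = c(10L, 40L, 100L), end = c(25L, 55L, 115L)
  ))$clusters
  expect_equal(replicate_concordance(a, ab), 66.7)
  # symmetry; vacuous agreement of two empty runs
  expect_equal(replicate_concordance(ab, a), 66.7)
  expect_equal(replicate_concordance(a[0], b[0]), 100.0)
})

test_that("sample summaries count distinct peptides per chain", {
  acc <- data.table::rbindlist(c(
    lapply(1:5, function(i) make_psm(peptide = fixture_chain(15, i),
                                     xcorr = 5)),
    list(make_psm(peptide = "AAAAACCCCCAAAAA", xcorr = 5),
         make_psm(peptide = "AAAAACCCCCAAAAA", xcorr = 4.9))))  # duplicate
  acc$tier <- "high"
  mp <- rbind(mapped_row("D01", s = 50L, e = 64L,
                         pep = acc$peptide[1]),
              mapped_row("D01", s = 50L, e = 64L,
                         pep = acc$peptide[1]),            # same peptide
              mapped_row("D01", chain = "LC", s = 20L, e = 34L,
                         pep = acc$peptide[2]))
  mp$sample_id <- "S1"
  ss <- sample_summaries(acc, mp)
  expect_equal(ss$n_total_peptides, 6L)   # duplicate collapses
  expect_equal(ss$n_hc_peptides, 1L)
  expect_equal(ss$n_lc_peptides, 1L)
  expect_equal(ss$pct_therapeutic, pct_therapeutic(1, 1, 6))
})

test_that("panel_report is deterministic and complete", {
  panel <- simulate_panel(small_config(seed = 41))
  acc <- data.table::rbindlist(lapply(split(panel$psm, by = "sample_id"),
                                      apply_filters))
  mapped <- map_panel(acc, panel$molecule, background = panel$background)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- panel_report(acc, mapped, panel$molecule, out_dir = d1)
  r2 <- panel_report(acc, mapped, panel$molecule, out_dir = d2)
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
  for (f in c("samples.tsv", "clusters.tsv", "frequencies.tsv",
              "lengths.tsv")) {
    expect_true(file.exists(file.path(d1, f)))
  }
  expect_equal(nrow(r1$samples), 3L)  # one row per sample
  expect_true(all(r1$clusters$frequency_pct >= 0 &
                    r1$clusters$frequency_pct <= 100))
  expect_true(isSymmetric(r1$concordance))
  # single-donor panel: frequencies only 0 or 100
  one <- r1$clusters
  acc1 <- acc[donor_id == "D01"]
  m1 <- mapped[mapped$donor_id == "D01"]
  r <- panel_report(acc1, m1, panel$molecule)
  expect_true(all(r$clusters$frequency_pct %in% c(0, 100)))
})
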
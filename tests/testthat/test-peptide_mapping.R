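test_that("map_peptide finds every placement", {
  mol <- make_molecule()
  # full LC -> one placement spanning the chain
  pl <- map_peptide(mol$chains$LC, mol)
  expect_equal(pl, data.frame(chain_id = "LC", start = 1L, end = 107L))
  # by-inspection example on a custom molecule
  m2 <- therapeutic_molecule("m", "AVVSVKWYAHRNDCEPQTGM",
                             "WYAHRNDCEPQTGMLAVVSK")
  expect_equal(map_peptide("VVSV", m2),
               data.frame(chain_id = "HC", start = 2L, end = 5L))
  # absent from both chains -> empty
  expect_equal(nrow(map_peptide("WWWW", mol)), 0L)
  # overlapping occurrences are all reported
  m3 <- therapeutic_molecule("m", "AAAAA", "CDEFG")
  expect_equal(map_peptide("AAAA", m3)$start, c(1L, 2L))
})

test_that("il_equivalent placements are a superset of exact ones", {
  m <- therapeutic_molecule("m", "KILVAGHKLLVAGH", "CDEFGHKNMW")
  exact <- map_peptide("ILVAGH", m, "exact")
  il <- map_peptide("ILVAGH", m, "il_equivalent")
  expect_equal(nrow(exact), 1L)
  expect_equal(il$start, c(2L, 9L))
  key <- function(df) paste(df$chain_id, df$start, df$end)
  expect_true(all(key(exact) %in% key(il)))
})

test_that("CDR overlap uses >= 1 shared residue", {
  mol <- make_molecule()  # HC CDR2 is 50..66, HC CDR3 is 97..110
  expect_equal(annotate_cdr_overlap("HC", 52L, 60L, mol), "HC CDR2")
  expect_equal(annotate_cdr_overlap("HC", 85L, 97L, mol), "HC CDR3")
  expect_equal(annotate_cdr_overlap("HC", 70L, 90L, mol), character(0))
  # brute-force residue-set intersection oracle on random intervals
  withr::with_seed(23, {
    for (i in 1:100) {
      s <- sample(1:110, 1); e <- min(120L, s + sample(8:20, 1))
      got <- annotate_cdr_overlap("HC", s, e, mol)
      cdrs <- mol$cdrs[mol$cdrs$chain_id == "HC", ]
      want <- cdrs$name[vapply(seq_len(nrow(cdrs)), function(k) {
        length(intersect(seq(s, e), seq(cdrs$start[k], cdrs$end[k]))) >= 1
      }, TRUE)]
      expect_identical(got, want)
    }
  })
})

test_that("uniqueness requires a therapeutic placement and no background hit", {
  mol <- make_molecule()
  bg <- c(BG1 = paste0("GGGG", substr(mol$chains$HC, 50, 60), "GGGG"),
          BG2 = "WYAHRNDCEPQTGM")
  expect_false(is_unique_to_therapeutic(substr(mol$chains$HC, 50, 60),
                                        mol, bg))
  expect_true(is_unique_to_therapeutic(substr(mol$chains$HC, 97, 110),
                                       mol, bg))
  expect_false(is_unique_to_therapeutic("WYAHRNDCEP", mol, bg))  # not mapped
})

test_that("length_statistics uses the lower median", {
  expect_equal(length_statistics(c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCC",
                                   "DDDDDDDDDDDDDDDDD"))$median, 16L)
  expect_equal(length_statistics(c(strrep("A", 14), strrep("C", 16)))$median,
               14L)
  empty <- length_statistics(character(0))
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$median))
  expect_equal(nrow(empty$histogram), 0L)
})

test_that("every map_panel placement reproduces its peptide by slicing", {
  panel <- simulate_panel(small_config(seed = 31))
  acc <- data.table::rbindlist(lapply(split(panel$psm, by = "sample_id"),
                                      apply_filters))
  mapped <- map_panel(acc, panel$molecule, background = panel$background)
  expect_gt(nrow(mapped), 0L)
  sliced <- mapply(function(ch, s, e) substr(panel$molecule$chains[[ch]],
                                             s, e),
                   mapped$chain_id, mapped$start, mapped$end)
  expect_identical(unname(sliced), mapped$peptide)
  expect_identical(mapped$end - mapped$start + 1L, nchar(mapped$peptide))
  # synthetic background never matches the chains, so truth is exact
  expect_true(all(mapped$unique_to_therapeutic))
})

test_that("localized modification positions are lifted to chain coordinates", {
  mol <- make_molecule()
  # molecule with a known M at HC residue 13
  hc <- paste0(substr(mol$chains$HC, 1, 12), "M",
               substr(mol$chains$HC, 14, 120))
  m2 <- therapeutic_molecule("m", hc, mol$chains$LC)
  pep <- substr(hc, 10, 21)
  rec <- make_psm(peptide = pep, mods = "M4(ox)", xcorr = 5)
  acc <- apply_filters(rec, filter_config())
  mapped <- map_panel(acc, m2)
  expect_equal(mapped$start, 10L)
  expect_equal(mapped$mods_chain, "M13(ox)")
})
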
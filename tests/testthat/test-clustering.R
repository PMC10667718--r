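iv_table <- function(start, end, chain = "HC") {
  data.table::data.table(chain_id = chain, start = as.integer(start),
                         end = as.integer(end),
                         peptide = sprintf("p%d_%d", start, end),
                         donor_id = "D01", sample_id = "S1")
}

test_that("build_clusters reproduces the worked examples", {
  # identical intervals collapse to one cluster, core = envelope
  cl <- build_clusters(iv_table(c(10, 10, 10), c(24, 24, 24)))
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$core_start, 10L)
  expect_equal(cl$clusters$core_end, 24L)
  expect_equal(cl$clusters$envelope_start, 10L)
  expect_equal(cl$clusters$envelope_end, 24L)

  # staggered ladder shrinks the core and extends the envelope
  cl <- build_clusters(iv_table(c(1, 3, 5), c(15, 17, 19)), 9L)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(unlist(cl$clusters[, .(core_start, core_end,
                                      envelope_start, envelope_end)]),
               c(core_start = 5L, core_end = 15L,
                 envelope_start = 1L, envelope_end = 19L))

  # disjoint intervals never merge
  cl <- build_clusters(iv_table(c(1, 40), c(15, 55)))
  expect_equal(nrow(cl$clusters), 2L)

  # numbering: HC before LC, then envelope start
  mp <- rbind(iv_table(c(100, 1), c(115, 16)),
              iv_table(30, 45, chain = "LC"))
  cl <- build_clusters(mp)
  expect_equal(cl$clusters$chain_id, c("HC", "HC", "LC"))
  expect_equal(cl$clusters$envelope_start, c(1L, 100L, 30L))
  expect_equal(cl$clusters$cluster_id, 1:3)
})

test_that("greedy clustering refines the connected-components oracle", {
  withr::with_seed(17, {
    for (trial in 1:200) {
      n <- sample(2:12, 1)
      s <- sample(1:80, n, replace = TRUE)
      e <- s + sample(8:20, n, replace = TRUE)
      mp <- iv_table(s, e)[!duplicated(paste(start, end))]
      cl <- build_clusters(mp, 9L)
      # partition: each interval in exactly one cluster
      expect_equal(nrow(cl$members), nrow(mp))
      expect_false(anyNA(cl$members$cluster_id))
      # every member contains its cluster core
      j <- merge(cl$members, cl$clusters, by = c("cluster_id", "chain_id"))
      expect_true(all(j$start <= j$core_start & j$end >= j$core_end))
      expect_true(all(j$core_end - j$core_start + 1L >= 9L))
      # refinement: a greedy cluster never straddles two components
      comp <- component_oracle(mp$start, mp$end, 9L)
      key <- paste(mp$start, mp$end)
      mcomp <- comp[match(paste(cl$members$start, cl$members$end), key)]
      expect_true(all(tapply(mcomp, cl$members$cluster_id,
                             function(x) length(unique(x)) == 1L)))
      # equality when every component shares a >= 9-residue common segment
      common <- tapply(seq_len(nrow(mp)), comp, function(ix) {
        min(mp$end[ix]) - max(mp$start[ix]) + 1L
      })
      if (all(common >= 9L)) {
        expect_equal(data.table::uniqueN(cl$members$cluster_id),
                     length(unique(comp)))
      }
    }
  })
})

test_that("presentation frequency rounds half-up to one decimal", {
  expect_equal(cluster_presentation_frequency(5, 7), 71.4)
  expect_equal(cluster_presentation_frequency(0, 7), 0.0)
  expect_equal(cluster_presentation_frequency(18, 18), 100.0)
  expect_equal(cluster_presentation_frequency(1, 3), 33.3)
  expect_error(cluster_presentation_frequency(1, 0), ">= 1")
  expect_error(cluster_presentation_frequency(8, 7), "more presenting")
})

test_that("cross-run cluster matching is greedy one-to-one by overlap", {
  a <- build_clusters(rbind(iv_table(73, 92), iv_table(150, 170)))$clusters
  # identical sets -> perfect pairing
  m <- match_clusters_across_runs(a, a)
  expect_equal(nrow(m), 2L)
  expect_equal(m$cluster_id_a, m$cluster_id_b)

  b <- build_clusters(iv_table(75, 94))$clusters
  m <- match_clusters_across_runs(a, b, 9L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$overlap, 18L)

  # same coordinates on different chains never match
  blc <- build_clusters(iv_table(73, 92, chain = "LC"))$clusters
  expect_equal(nrow(match_clusters_across_runs(a, blc)), 0L)
})
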
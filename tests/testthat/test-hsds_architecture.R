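test_that("conservation scores are modal frequencies with gap-majority zeros", {
  msa <- c("LAKG-", "LCKG-", "LDKGA", "LEKG-")
  p <- conservation_profile(msa, window = 1L)
  expect_equal(p$raw, c(1, 0.25, 1, 1, 0))
  expect_equal(p$n_sequences, 4L)
  expect_error(conservation_profile(c("AB", "ABC")), "ragged")
  expect_error(conservation_profile("AB"), ">= 2 rows")
  # planted block structure gives a high-low-high profile
  hc <- generate_hsds_cohort(hsds_config(cr_rate = 0), seed = 2)
  p2 <- conservation_profile(hc$alignment, window = 1L)
  segs <- hc$truth$segments
  crs <- segs[segs$label %in% c("N-CR", "cCR", "C-CR"), ]
  for (k in seq_len(nrow(crs)))
    expect_true(all(p2$raw[crs$start_col[k]:crs$end_col[k]] == 1))
  trds <- segs[grepl("TRD", segs$label), ]
  for (k in seq_len(nrow(trds)))
    expect_lt(mean(p2$raw[trds$start_col[k]:trds$end_col[k]]), 0.5)
})

test_that("TRD segmentation recovers planted boundaries and degenerate cases", {
  hc <- generate_hsds_cohort(hsds_config(), seed = 8)
  segs <- segment_trds(conservation_profile(hc$alignment, window = 9L))
  expect_equal(segs$label, c("N-CR", "TRD1", "cCR", "TRD2", "C-CR"))
  truth <- hc$truth$segments
  expect_true(all(abs(segs$start_col - truth$start_col) <= 9))
  expect_true(all(abs(segs$end_col - truth$end_col) <= 9))

  # fully conserved profile -> single CR, no TRD
  short <- generate_hsds_cohort(hsds_config(type = "short"), seed = 8)
  segs2 <- segment_trds(conservation_profile(short$alignment))
  expect_equal(segs2$label, "CR")

  # all-variable profile -> one capped TRD with a warning
  expect_warning(segs3 <- segment_trds(rep(0.1, 200)), "entirely variable")
  expect_equal(segs3$label, "TRD1")
  expect_equal(c(segs3$start_col, segs3$end_col), c(1L, 200L))

  # more than two qualifying variable runs: the two longest are kept
  prof <- c(rep(1, 60), rep(0, 55), rep(1, 60), rep(0, 80), rep(1, 60),
            rep(0, 70), rep(1, 60))
  expect_warning(segs4 <- segment_trds(prof), "two longest")
  expect_equal(sum(grepl("TRD", segs4$label)), 2L)
  trd_lens <- with(segs4[grepl("TRD", segs4$label), ],
                   end_col - start_col + 1)
  expect_equal(sort(trd_lens), c(70, 80))
})

test_that("segmentation is deterministic and shifts with prepended conserved columns", {
  hc <- generate_hsds_cohort(hsds_config(), seed = 21)
  p <- conservation_profile(hc$alignment, window = 9L)
  s1 <- segment_trds(p)
  expect_identical(segment_trds(p), s1)
  k <- 25L
  shifted <- vapply(hc$alignment, function(r) paste0(strrep("Q", k), r),
                    character(1))
  s2 <- segment_trds(conservation_profile(shifted, window = 9L))
  expect_equal(s2$start_col[-1], s1$start_col[-1] + k)
  expect_equal(s2$end_col, s1$end_col + k)
})

test_that("tandem tetrapeptide repeats match the brute-force oracle", {
  hits <- find_tandem_tetrapeptide_repeats("MGSTAELTAELTAELKQD")
  expect_equal(hits$unit, "TAEL")
  expect_equal(hits$count, 3L)
  expect_true(hits$tandem)
  expect_equal(nrow(find_tandem_tetrapeptide_repeats("ABCDABCE")), 0L)
  set.seed(59)
  for (i in 1:300) {
    s <- random_aa_str(sample(20:60, 1))
    if (i %% 2 == 0) {  # plant a tandem run to exercise the positive path
      unit <- random_aa_str(4)
      run <- strrep(unit, sample(2:4, 1))
      at <- sample(nchar(s), 1)
      s <- paste0(substr(s, 1, at), run, substr(s, at + 1, nchar(s)))
    }
    got <- find_tandem_tetrapeptide_repeats(s)
    want <- oracle_tandem4(s)
    expect_equal(nrow(got), length(want), info = s)
    if (length(want)) {
      expect_equal(got$unit, vapply(want, `[[`, character(1), "unit"))
      expect_equal(got$count, vapply(want, `[[`, integer(1), "count"))
      expect_equal(got$start, vapply(want, `[[`, integer(1), "start"))
    }
  }
})

test_that("short gapped repeats are found with maximal-unit preference", {
  hits <- find_short_repeats("AWLEEQKGHMLEEQKYV", max_gap = 5L)
  expect_equal(hits$unit, "LEEQK")
  expect_equal(hits$count, 2L)
  expect_false(hits$tandem)
  expect_equal(hits$gaps, "3")

  hits2 <- find_short_repeats("LEEQKLEEQK")
  expect_equal(hits2$unit, "LEEQK")
  expect_true(hits2$tandem)

  # copies separated by more than max_gap are not chained
  far <- paste0("LEEQK", "ACDFGHIMNP", "LEEQK")
  expect_equal(nrow(find_short_repeats(far, max_gap = 5L)), 0L)

  # sub-units of a reported longer unit are suppressed, distinct units are not
  both <- paste0("WNDYRH", "LEEQK", "GHM", "LEEQK", "FCP",
                 "TAEL", "VV", "TAEL", "IMSW")
  h <- find_short_repeats(both, max_gap = 5L)
  expect_setequal(h$unit, c("LEEQK", "TAEL"))
})

test_that("spacer/repeat cross-tabulation flags violations of an expected map", {
  rec <- data.frame(repeat_count = c(2, 2), spacer_len = c(6, 5))
  out <- correlate_spacer_repeats(rec, expected = list("2" = c(6, 7)))
  expect_equal(nrow(out$flagged), 1L)
  expect_equal(out$flagged$spacer_len, 5)
  out2 <- correlate_spacer_repeats(rec)
  expect_equal(nrow(out2$flagged), 0L)
  expect_equal(sum(out2$table), 2)
})

test_that("aligned FASTA and Clustal alignments are read identically", {
  rows <- c(seq1 = "MK-LV", seq2 = "MKALV")
  fa <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">seq1", "MK-LV", ">seq2", "MKALV"), fa)
  expect_equal(read_alignment(fa), rows)
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.82) multiple sequence alignment", "", "",
               "seq1            MK-LV", "seq2            MKALV",
               "                **.**"), cl)
  expect_equal(read_alignment(cl, format = "clustal"), rows)
})
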
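test_that("reverse complement reproduces published motif pairs and is an involution", {
  expect_equal(reverse_complement("TCANNNNNNCTC"), "GAGNNNNNNTGA")
  expect_equal(reverse_complement("GCATC"), "GATGC")
  expect_equal(reverse_complement("ACCNNNNNRTGT"), "ACAYNNNNNGGT")
  expect_equal(reverse_complement("GACNNNNNTGT"), "ACANNNNNGTC")
  expect_equal(reverse_complement("CACNNNNRTTG"), "CAAYNNNNGTG")

  set.seed(11)
  for (i in 1:50) {
    m <- random_iupac_motif(sample(4:14, 1), sample(0:4, 1))
    expect_identical(reverse_complement(reverse_complement(m)), m)
  }
  expect_error(degenerate_motif("GAQC"), "invalid IUPAC")
  # modified-base compatibility
  expect_error(degenerate_motif("GATC", modified_pos = 1, mod_type = "m6A"),
               "incompatible")
  m <- degenerate_motif("TCANNNNNNCTC", modified_pos = 3, mod_type = "m6A")
  expect_s3_class(reverse_complement(m), "DegenerateMotif")
  expect_true(is.na(reverse_complement(m)$modified_pos))
})

test_that("bipartite decomposition finds the spacer and reassembles the pattern", {
  d <- bipartite_decompose("TCANNNNNNCTC")
  expect_equal(list(d$half1, d$spacer_len, d$half2), list("TCA", 6L, "CTC"))
  d2 <- bipartite_decompose("ACCNNNNNRTGT")
  expect_equal(list(d2$half1, d2$spacer_len, d2$half2), list("ACC", 5L, "RTGT"))
  expect_null(bipartite_decompose("GATC"))
  expect_null(bipartite_decompose("GATGC"))        # no internal N run
  expect_null(bipartite_decompose("NNNGATC"))      # run touches the edge
  expect_warning(d3 <- bipartite_decompose("TCANNNCTCNNNTGA"),
                 "leftmost")
  # reassembly identity on decomposable patterns
  for (pat in c("TCANNNNNNCTC", "ACCNNNNNRTGT", "GACNNNNNTGT",
                "CACNNNNRTTG")) {
    d <- bipartite_decompose(pat)
    expect_identical(paste0(d$half1, strrep("N", d$spacer_len), d$half2), pat)
  }
})

test_that("palindromy is equivalent to equality with the reverse complement", {
  expect_true(is_palindromic("GATC"))
  expect_false(is_palindromic("GCATC"))
  expect_true(is_palindromic("ACCNNNNNGGT"))
  expect_true(is_palindromic("TCANNNNNNTGA"))
  set.seed(7)
  for (i in 1:50) {
    m <- random_iupac_motif(sample(3:10, 1), sample(0:3, 1))
    expect_identical(is_palindromic(m), identical(m, reverse_complement(m)))
  }
})

test_that("genome scanning matches the exhaustive oracle and deduplicates palindromes", {
  # duplex view of an asymmetric pair: GATGC is a + hit where GCATC is the
  # - hit at the same site
  expect_equal(scan_motif("GGATGCAA", "GATGC"),
               data.frame(position = 2L, strand = "+"),
               ignore_attr = TRUE)
  expect_equal(scan_motif("GGATGCAA", "GCATC"),
               data.frame(position = 2L, strand = "-"),
               ignore_attr = TRUE)
  # palindromic dedup: 2 duplex sites
  hits <- scan_motif("GATCGATC", "GATC")
  expect_equal(hits$position, c(1L, 5L))
  expect_true(all(hits$strand == "+"))
  expect_equal(nrow(scan_motif("", "GATC")), 0L)
  # origin-spanning match on a circular replicon
  circ <- scan_motif("AACCT", "CTAA", circular = TRUE)
  expect_equal(circ, data.frame(position = 4L, strand = "+"),
               ignore_attr = TRUE)
  expect_equal(nrow(scan_motif("AACCT", "CTAA", circular = FALSE)), 0L)

  set.seed(23)
  for (i in 1:200) {
    seq <- random_dna_str(sample(20:80, 1),
                          alphabet = c("A", "C", "G", "T", "N"))
    pat <- random_iupac_motif(sample(3:7, 1), sample(0:2, 1))
    circular <- i %% 3 == 0
    got <- scan_motif(seq, pat, circular = circular)
    want <- oracle_scan(seq, pat, circular = circular)
    expect_equal(got$position, want$position,
                 info = paste(seq, pat, circular))
    expect_equal(got$strand, want$strand)
  }
})

test_that("scan count on planted genomes equals planted plus background occurrences", {
  set.seed(5)
  base <- random_dna_str(4000)
  planted <- plant_motif_sites(base, "TCANNNNNNCTC", 40, seed = 5)
  hits <- scan_motif(planted$sequence, "TCANNNNNNCTC")
  want <- oracle_scan(planted$sequence, "TCANNNNNNCTC")
  expect_equal(hits$position, want$position)
  expect_gte(sum(hits$strand == "+"), 40L)
  expect_true(all(planted$positions %in% hits$position[hits$strand == "+"]))
})

test_that("modification fraction uses half-up rounding at the printed precision", {
  expect_equal(modification_fraction(1118, 1192, 2), 0.94)
  expect_equal(modification_fraction(14333, 14382, 3) * 100, 99.7)
  expect_equal(modification_fraction(0, 10, 2), 0)
  expect_equal(modification_fraction(1, 8, 2), 0.13)   # 0.125 rounds up
  expect_error(modification_fraction(1, 0), "n_genome")
  expect_error(modification_fraction(5, 3), "n_detected")
  for (n in c(1, 7, 1192)) expect_equal(modification_fraction(n, n, 2), 1)
})

test_that("half-site deletion predicts a palindromic symmetrized motif", {
  d <- bipartite_decompose("TCANNNNNNCTC")
  expect_equal(predict_half_site_motif(d, "first")$pattern, "TCANNNNNNTGA")
  d2 <- bipartite_decompose("ACCNNNNNRTGT")
  expect_equal(predict_half_site_motif(d2, "first")$pattern, "ACCNNNNNGGT")
  set.seed(31)
  for (i in 1:20) {
    h <- random_iupac_motif(sample(3:4, 1), 0)
    s <- sample(4:8, 1)
    d <- structure(list(half1 = h, spacer_len = s, half2 = "GGG"),
                   class = "BipartiteDecomposition")
    for (side in c("first", "second"))
      expect_true(is_palindromic(predict_half_site_motif(d, side)))
  }
})
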
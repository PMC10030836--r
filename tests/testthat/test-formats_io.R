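test_that("GenBank writer output round-trips through the reader", {
  syn <- generate_strain(strain_config(c("hsdRSMS", "hsdMSR", "typeIV")),
                         seed = 101)
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(syn$records, path)
  back <- read_genbank(path)
  expect_length(back, length(syn$records))
  for (i in seq_along(back)) {
    a <- syn$records[[i]]; b <- back[[i]]
    expect_identical(b$replicon_id, a$replicon_id)
    expect_identical(b$sequence, a$sequence)
    expect_identical(b$source_kind, a$source_kind)
    expect_identical(b$genes$start, a$genes$start)
    expect_identical(b$genes$end, a$genes$end)
    expect_identical(b$genes$strand, a$genes$strand)
    expect_identical(b$genes$product, a$genes$product)
    expect_identical(b$genes$aa_seq, a$genes$aa_seq)
  }
})

test_that("GenBank reader counts records and genes, and collapses join() locations", {
  gbk <- c(
    "LOCUS       testrep1 60 bp    DNA     linear   BCT 01-JAN-2026",
    "DEFINITION  test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             1..9",
    '                     /locus_tag="g1"',
    '                     /product="protein one"',
    "     CDS             complement(11..19)",
    '                     /locus_tag="g2"',
    '                     /product="protein two"',
    "     CDS             join(21..26,31..36)",
    '                     /locus_tag="g3"',
    '                     /product="split protein"',
    "     CDS             41..49",
    '                     /locus_tag="g4"',
    '                     /product="protein four"',
    "ORIGIN",
    sprintf("%9d %s", 1, paste(rep("acgtacgtac", 6), collapse = " ")),
    "//")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gbk, path)
  expect_warning(recs <- read_genbank(path), "join|collapsed")
  expect_length(recs, 1L)
  expect_equal(nrow(recs[[1]]$genes), 4L)
  g3 <- recs[[1]]$genes[recs[[1]]$genes$locus_tag == "g3", ]
  expect_equal(c(g3$start, g3$end), c(21L, 36L))
  expect_equal(recs[[1]]$genes$strand, c("+", "-", "+", "+"))
  # malformed file
  bad <- withr::local_tempfile()
  writeLines("not a genbank file", bad)
  expect_error(read_genbank(bad), "LOCUS")
})

test_that("motif summary parsing handles dialects, synonyms and validation", {
  header <- "MotifString,CenterPos,Mod,Fraction,nDetected,nGenome,MeanScore,MeanCov"
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header, "TCANNNNNNCTC,3,m6A,0.94,1118,1192,880,632.6"), path)
  obs <- read_motif_summary(path)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$fraction, 0.94)
  expect_equal(obs$n_detected, 1118L)
  expect_equal(obs$center_pos, 3L)

  # header only -> empty
  writeLines(header, path)
  expect_equal(nrow(read_motif_summary(path)), 0L)

  # tab dialect with synonym headers, extra column preserved
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("motifString", "centerPos", "mod", "fraction",
                     "nDetected", "nGenome", "meanScore", "meanCoverage",
                     "groupTag", sep = "\t"),
               paste("GATC", "2", "m6A", "1.00", "37673", "37676", "1408",
                     "632.5", "dam", sep = "\t")), path2)
  obs2 <- read_motif_summary(path2)
  expect_equal(obs2$motif_string, "GATC")
  expect_equal(attr(obs2, "extra")$groupTag, "dam")

  # missing mandatory column
  writeLines(c("MotifString,CenterPos,Mod,Fraction", "GATC,2,m6A,1.0"), path)
  expect_error(read_motif_summary(path), "n_detected")

  # fraction/count mismatch beyond rounding
  writeLines(c(header, "GATC,2,m6A,0.94,10,1000,100,100"), path)
  expect_warning(read_motif_summary(path), "mismatch")

  # n_detected > n_genome
  writeLines(c(header, "GATC,2,m6A,1.0,2000,1000,100,100"), path)
  expect_error(read_motif_summary(path), "n_detected > n_genome")
})

test_that("base-modification GFF3 round-trips and requires strand", {
  syn <- generate_strain(seed = 7)
  sim <- simulate_motif_report(syn$records[[1]],
                               degenerate_motif("GATC", 2, "m6A"),
                               true_fraction = 0.8, seed = 7)
  path <- withr::local_tempfile(fileext = ".gff")
  write_basemod_gff(sim$sites, path)
  back <- read_basemod_gff(path)
  expect_equal(nrow(back), nrow(sim$sites))
  expect_equal(back$position, sim$sites$position)
  expect_equal(back$strand, sim$sites$strand)
  expect_equal(back$coverage, sim$sites$coverage)
  expect_equal(back$ipd_ratio, sim$sites$ipd_ratio)

  lines <- c("##gff-version 3",
             "chr1\tkinModCall\tm6A\t100\t100\t35\t+\t.\tcoverage=120;context=AATC;IPDRatio=4.10",
             "chr1\tkinModCall\tm6A\t205\t205\t21\t-\t.\tcoverage=80;context=GGTC;IPDRatio=2.20",
             "chr1\tkinModCall\tmodified_base\t300\t300\t10\t+\t.\tcoverage=50;context=TTTT;IPDRatio=1.90")
  writeLines(lines, path)
  expect_equal(nrow(read_basemod_gff(path)), 3L)

  writeLines(c(lines[1:2],
               "chr1\tkinModCall\tm6A\t401\t401\t9\t.\t.\tcoverage=9;context=AA;IPDRatio=1.2"),
             path)
  expect_error(read_basemod_gff(path), "401")
})

test_that("the packaged inventory fixture loads intact", {
  fx <- load_table1_fixture()
  expect_equal(length(unique(fx$strain)), 14L)
  r1 <- fx[fx$locus_tag == "JGY91_01640", ]
  expect_equal(r1$nt_len, 198L)
  expect_true(r1$truncated_flag)
  expect_equal(r1$declared_class, "I")
  r2 <- fx[fx$locus_tag == "JGY90_14125", ]
  expect_equal(r2$nt_len, 576L)
  expect_equal(r2$declared_class, "I")
  expect_false(r2$truncated_flag)
  # uncertain replicon attribution is parsed to "unknown", raw kept
  r3 <- fx[fx$locus_tag == "LHJ66_13490", ]
  expect_equal(r3$location, "unknown")
  expect_equal(r3$location_raw, "plasmid?")
})

test_that("Newick writing quotes labels, rejects duplicates and round-trips", {
  tr <- read_newick(text = "(A:1,B:2);")
  expect_equal(write_newick(tr), "(A:1,B:2);")
  dup <- tr; dup$tip.label <- c("A", "A")
  expect_error(write_newick(dup), "duplicate")
  sp <- tr; sp$tip.label <- c("taxon one", "B")
  expect_match(write_newick(sp), "'taxon one'", fixed = TRUE)
  set.seed(13)
  for (i in 1:10) {
    t0 <- ape::rtree(sample(3:10, 1))
    back <- read_newick(text = write_newick(t0))
    expect_equal(sort(back$tip.label), sort(t0$tip.label))
    d0 <- ape::cophenetic.phylo(t0)
    d1 <- ape::cophenetic.phylo(back)[rownames(d0), colnames(d0)]
    expect_equal(d1, d0, tolerance = 1e-6)
  }
})
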
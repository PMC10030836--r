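test_that("gene classification follows keyword and length rules", {
  s <- classify_rm_gene("Type I restriction endonuclease subunit S", 1170)
  expect_equal(s$role, "hsdS")
  expect_false(s$truncated)
  expect_true(length(s$evidence) > 0)

  iig <- classify_rm_gene("DEAD/DEAH box helicase", 4737,
                          adjacent_mtase = FALSE)
  expect_equal(iig$role, "fused_IIG")
  expect_equal(iig$rm_class, "IIG")

  res <- classify_rm_gene("DEAD/DEAH box helicase family protein", 2700,
                          adjacent_mtase = TRUE)
  expect_equal(res$role, "res_III")
  expect_equal(res$rm_class, "III")

  tr <- classify_rm_gene("Type I restriction modification subunit M", 198)
  expect_equal(tr$role, "hsdM")
  expect_true(tr$truncated)

  none <- classify_rm_gene("", NA)
  expect_equal(none$role, "unknown")
  expect_equal(none$rm_class, "none")
})

test_that("every fixture row's computed class equals its declared class", {
  cls <- classify_fixture(load_table1_fixture())
  mismatch <- cls[cls$computed_class != cls$declared_class, , drop = FALSE]
  expect_equal(nrow(mismatch), 0L,
               info = paste("divergent locus tags:",
                            paste(mismatch$locus_tag, collapse = ", ")))
  # every printed truncation marker is reproduced by the length-floor
  # heuristic, which additionally flags the fragmentary 423 nt hsdR
  hsd <- cls[cls$role %in% c("hsdR", "hsdM", "hsdS"), ]
  expect_true(all(hsd$truncated[hsd$truncated_flag]))
  expect_true(all(cls$truncated[cls$truncated_flag]))
  expect_true(cls$truncated[cls$locus_tag == "SXYL_RS00155"])
})

test_that("operon reconstruction labels the known topologies", {
  # plasmid-style four-gene arrangement: R, S_short, M, S_long in
  # transcription order (minus strand here), with the hsdM/hsdS_long overlap
  g <- rbind(
    gene_row("p_04", 100, 1269, "-", "Type I restriction endonuclease subunit S"),
    gene_row("p_03", 1262, 2818, "-", "Type I restriction modification system subunit M"),
    gene_row("p_02", 2850, 3425, "-", "Type I restriction endonuclease subunit S"),
    gene_row("p_01", 3460, 6246, "-", "Type I restriction endonuclease subunit R"))
  ops <- reconstruct_operons(classify_gene_table(g), "plasmid1")
  expect_length(ops, 1L)
  expect_equal(ops[[1]]$topology, "hsdRSMS")
  expect_true(ops[[1]]$complete)
  expect_equal(ops[[1]]$overlaps$overlap_bp, 8L)
  expect_equal(ops[[1]]$genes$role, c("hsdR", "hsdS", "hsdM", "hsdS"))

  g2 <- rbind(
    gene_row("c_01", 100, 1614, "+", "Type I restriction modification subunit M"),
    gene_row("c_02", 1700, 2914, "+", "Type I restriction endonuclease subunit S"),
    gene_row("c_03", 3000, 6122, "+", "Type I restriction endonuclease subunit R"))
  ops2 <- reconstruct_operons(classify_gene_table(g2), "chrom1")
  expect_equal(ops2[[1]]$topology, "hsdMSR")
  expect_true(ops2[[1]]$complete)

  # lone truncated hsdM -> single, incomplete
  g3 <- gene_row("t_01", 100, 297, "+", "Type I restriction modification subunit M")
  ops3 <- reconstruct_operons(classify_gene_table(g3), "chrom2")
  expect_equal(ops3[[1]]$topology, "single")
  expect_false(ops3[[1]]$complete)

  # a gap beyond max_gap splits the run
  g4 <- rbind(
    gene_row("c_01", 100, 1614, "+", "Type I restriction modification subunit M"),
    gene_row("c_02", 3000, 4214, "+", "Type I restriction endonuclease subunit S"))
  ops4 <- reconstruct_operons(classify_gene_table(g4), "chrom3")
  expect_length(ops4, 2L)

  # strandless genes are excluded with a warning
  g5 <- rbind(g2, gene_row("c_04", 6500, 7000, ".",
                           "Type I restriction endonuclease subunit S"))
  expect_warning(ops5 <- reconstruct_operons(classify_gene_table(g5), "chrom4"),
                 "strand")
  expect_length(ops5, 1L)
})

test_that("operon topology is invariant under reverse-complementing the replicon", {
  syn <- generate_strain(strain_config(c("hsdRSMS", "hsdMSR", "typeIII")),
                         seed = 55)
  for (rec in syn$records) {
    g <- classify_gene_table(rec$genes)
    ops_fwd <- reconstruct_operons(g, rec$replicon_id)
    L <- nchar(rec$sequence)
    g_rc <- g
    g_rc$start <- L - g$end + 1L
    g_rc$end <- L - g$start + 1L
    g_rc$strand <- ifelse(g$strand == "+", "-", "+")
    g_rc <- g_rc[order(g_rc$start), ]
    ops_rc <- reconstruct_operons(classify_gene_table(g_rc), rec$replicon_id)
    expect_equal(vapply(ops_rc, `[[`, character(1), "topology"),
                 vapply(ops_fwd, `[[`, character(1), "topology"))
    expect_equal(lapply(ops_rc, function(o) o$genes$role),
                 lapply(ops_fwd, function(o) o$genes$role))
  }
})

test_that("gene overlap equals the interval-intersection oracle", {
  a <- list(start = 100, end = 1656); b <- list(start = 1649, end = 2848)
  expect_equal(detect_overlap(a, b), 8L)
  expect_equal(detect_overlap(list(start = 100, end = 200),
                              list(start = 300, end = 400)), 0L)
  expect_equal(detect_overlap(list(start = 100, end = 200),
                              list(start = 150, end = 400)), 51L)
  expect_error(detect_overlap(list(start = 1, end = 5, replicon_id = "r1"),
                              list(start = 2, end = 6, replicon_id = "r2")),
               "replicon")
  set.seed(17)
  for (i in 1:200) {
    # neighbor geometry: b starts at or after a and extends at least as far
    as <- sample(1:500, 1); ae <- as + sample(0:300, 1)
    bs <- sample(as:600, 1); be <- max(ae, bs) + sample(0:300, 1)
    got <- detect_overlap(list(start = as, end = ae),
                          list(start = bs, end = be))
    want <- if (bs > ae) 0L else oracle_overlap(as, ae, bs, be)
    expect_equal(got, want)
  }
})

test_that("Shine-Dalgarno detection recovers planted sites and rejects noise", {
  up <- paste0(strrep("C", 20), "AGGAGG", "TTAACAT")  # SD ends 7 nt upstream
  hit <- find_shine_dalgarno(up)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$dist_to_start, 7L)
  expect_null(find_shine_dalgarno(""))
  # spacing constraint: SD directly abutting the start codon does not count
  expect_null(find_shine_dalgarno(paste0(strrep("C", 20), "AGGAGG", "TT")))
  # sequences without a >= 5-of-6 match in the window yield nothing
  set.seed(3)
  for (i in 1:50) {
    up <- random_dna_str(40)
    hit <- find_shine_dalgarno(up)
    if (!is.null(hit)) {
      window <- substr(up, hit$position, hit$position + 5L)
      expect_lte(sum(strsplit(window, "")[[1]] !=
                       strsplit("AGGAGG", "")[[1]]), 1L)
    }
  }
})

test_that("sigma-70 promoter detection enforces spacer limits and breaks ties", {
  up <- paste0(strrep("C", 30), "TTGACA", strrep("A", 17), "TATAAT",
               strrep("C", 40))
  hit <- find_sigma70_promoter(up)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$spacer, 17L)
  expect_equal(hit$position, 31L)
  # spacer out of range
  up25 <- paste0(strrep("C", 30), "TTGACA", strrep("A", 25), "TATAAT",
                 strrep("C", 40))
  expect_null(find_sigma70_promoter(up25))
  # two equal-score candidates: nearest the gene start wins, with a warning
  one <- paste0("TTGACA", strrep("G", 17), "TATAAT")
  up2 <- paste0(one, strrep("C", 10), one, strrep("C", 20))
  expect_warning(hit2 <- find_sigma70_promoter(up2), "equal-score")
  expect_equal(hit2$position, nchar(one) + 10L + 1L)
})

test_that("per-strain completeness matches the published tallies", {
  inv <- run_inventory(fixture = TRUE)
  expect_equal(inv$summary$n_strains, 14L)
  expect_equal(inv$summary$complete_type_I, 7L)
  expect_equal(inv$summary$type_IIG, 3L)
  comp <- inv$completeness
  expect_false(comp$complete_type_I[comp$strain == "C2a"])
  expect_false(comp$complete_type_I[comp$strain == "TMW 2.1521"])
  expect_true(comp$complete_type_I[comp$strain == "TMW 2.1023"])
  expect_true(all(comp$type_IIG == comp$strain %in%
                    c("TMW 2.1521", "TMW 2.1523", "TMW 2.1780")))
  expect_true(comp$complete_type_IV[comp$strain == "C2a"])
})

test_that("CDS length converts to protein length with the stop removed", {
  expect_equal(protein_length_from_cds(576), 191L)
  expect_equal(protein_length_from_cds(6), 1L)
  expect_equal(protein_length_from_cds(1557), 518L)
  expect_error(protein_length_from_cds(577), "frame")
  expect_error(protein_length_from_cds(3), "codon")
})
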
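# Seeded synthetic-data generators: annotated replicons with planted RM
# operons, simulated SMRT motif reports, HsdS alignment cohorts, and
# cross-strain motif/gene-family linkage cohorts — each with machine-readable
# ground truth, so every pipeline stage runs and is testable offline.

.SYN_PRODUCTS <- c(
  hsdR = "Type I restriction endonuclease subunit R",
  hsdM = "Type I restriction modification subunit M",
  hsdS = "Type I restriction endonuclease subunit S",
  mod_III = "Site-specific DNA methyltransferase",
  res_III = "DEAD/DEAH box helicase family protein",
  mcrB_like = "DUF3578 domain-containing protein_McrBP",
  mcrC_like = "Hypothetical protein_McrCP",
  fused_IIG = "DEAD/DEAH box helicase")

# role sequences (transcription order) and gene lengths for planted operons,
# mirroring observed staphylococcal systems
.SYN_TOPOLOGIES <- list(
  hsdRSMS = list(roles = c("hsdR", "hsdS", "hsdM", "hsdS"),
                 lens = c(2787L, 576L, 1557L, 1170L)),
  hsdMSR = list(roles = c("hsdM", "hsdS", "hsdR"),
                lens = c(1515L, 1215L, 3123L)),
  typeIII = list(roles = c("mod_III", "res_III"), lens = c(2001L, 2700L)),
  typeIV = list(roles = c("mcrB_like", "mcrC_like"), lens = c(2028L, 1323L)),
  IIG = list(roles = "fused_IIG", lens = 4737L))

.random_dna <- function(n, gc = 0.33) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random CDS content: ATG + random non-stop codons + TAA
.random_cds <- function(nt_len, gc = 0.33) {
  stopifnot(nt_len %% 3L == 0L, nt_len >= 6L)
  n_codon <- nt_len %/% 3L - 2L
  bases <- c("A", "C", "G", "T")
  codons <- replicate(n_codon, paste(sample(bases, 3, replace = TRUE,
                                            prob = c((1 - gc) / 2, gc / 2,
                                                     gc / 2, (1 - gc) / 2)),
                                     collapse = ""))
  stops <- c("TAA", "TAG", "TGA")
  codons[codons %in% stops] <- "AAA"
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

.random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

#' Default configuration for the strain generator
#'
#' One replicon per topology entry. Defaults emulate the observed systems:
#' an hsdRSMS plasmid (8 bp hsdM/hsdS_long overlap, Shine-Dalgarno site
#' before every ORF, sigma-70 promoters before hsdR and hsdS_short) plus a
#' chromosome-like replicon carrying an hsdMSR operon. Background base
#' composition is i.i.d. with GC 0.33 (staphylococcal-like).
#'
#' @param topologies Character vector of topologies to plant, one replicon
#'   each (subset of `hsdRSMS, hsdMSR, typeIII, typeIV, IIG`).
#' @param replicon_len Replicon length (nt).
#' @param overlap hsdM/hsdS_long overlap for hsdRSMS (bp).
#' @param gap Intergenic gap inside operons (nt).
#' @param gc Background GC content.
#' @param strand Strand the operon is planted on.
#' @return Config list for [generate_strain()].
#' @export
strain_config <- function(topologies = c("hsdRSMS", "hsdMSR"),
                          replicon_len = 12000L, overlap = 8L, gap = 30L,
                          gc = 0.33, strand = "+") {
  list(topologies = topologies, replicon_len = as.integer(replicon_len),
       overlap = as.integer(overlap), gap = as.integer(gap), gc = gc,
       strand = strand)
}

#' Generate a synthetic annotated strain with planted RM operons
#'
#' Plants one operon per requested topology, each on its own replicon, with
#' annotation text drawn from the standard vocabulary, Shine-Dalgarno sites
#' (`AGGAGG` ending 7 nt upstream) before every planted ORF, sigma-70
#' promoter boxes (`TTGACA` + 17 nt + `TATAAT`) before the operon and —
#' for hsdRSMS — before hsdS_short, and the configured hsdM/hsdS_long
#' overlap. Fully deterministic given `seed`.
#'
#' @param config From [strain_config()].
#' @param seed Integer seed.
#' @param strain Strain name used in replicon ids.
#' @return List with `records` (list of `GenomeRecord`) and `truth`
#'   (planted operon coordinates, roles, overlaps, regulatory positions).
#' @export
generate_strain <- function(config = strain_config(), seed = 1L,
                            strain = "syn1") {
  set.seed(seed)
  records <- list()
  truth <- list(seed = seed, operons = list())
  for (t in config$topologies) {
    topo <- .SYN_TOPOLOGIES[[t]]
    if (is.null(topo)) stop("unknown topology: ", t)
    lens <- topo$lens
    overlaps <- rep(config$gap, length(lens) - 1L)  # positive = gap
    if (t == "hsdRSMS") overlaps[3] <- -config$overlap
    if (t == "typeIV") overlaps[1] <- -4L  # tandem overlapping reading frames
    total <- sum(lens) + sum(pmax(overlaps, 0L)) + 600L
    if (total > config$replicon_len)
      stop("config error: operon does not fit the replicon (needs ", total,
           " nt)")
    replicon_id <- paste0(strain, "_", t)
    seq <- .random_dna(config$replicon_len, config$gc)
    start0 <- 301L
    starts <- integer(length(lens)); ends <- integer(length(lens))
    pos <- start0
    for (i in seq_along(lens)) {
      starts[i] <- pos
      ends[i] <- pos + lens[i] - 1L
      pos <- ends[i] + 1L + (if (i < length(lens)) overlaps[i] else 0L)
    }
    # write CDS content, in order; overlapping genes share the junction
    for (i in seq_along(lens))
      substr(seq, starts[i], ends[i]) <- .random_cds(lens[i], config$gc)
    # Shine-Dalgarno before each ORF (3' end 7 nt upstream of start)
    sd_pos <- integer(0)
    for (s in starts) {
      if (s - 13L >= 1L) {
        substr(seq, s - 13L, s - 8L) <- "AGGAGG"
        sd_pos <- c(sd_pos, s - 13L)
      }
    }
    # sigma-70 promoter upstream of the operon (and of hsdS_short in hsdRSMS)
    promoter_targets <- starts[1]
    if (t == "hsdRSMS") promoter_targets <- c(promoter_targets, starts[2])
    prom_pos <- integer(0)
    for (s in promoter_targets) {
      p35 <- s - 75L
      if (p35 >= 1L) {
        substr(seq, p35, p35 + 5L) <- "TTGACA"
        substr(seq, p35 + 23L, p35 + 28L) <- "TATAAT"
        prom_pos <- c(prom_pos, p35)
      }
    }
    roles <- topo$roles
    genes <- data.frame(
      locus_tag = sprintf("%s_%s_%02d", strain, t, seq_along(lens)),
      start = starts, end = ends, strand = config$strand,
      product = unname(.SYN_PRODUCTS[roles]),
      nt_len = lens,
      aa_seq = vapply(lens, function(l) .random_aa(l %/% 3L - 1L),
                      character(1)),
      stringsAsFactors = FALSE)
    if (config$strand == "-") {
      # mirror the layout so transcription order is preserved on the minus
      # strand: coordinates are reflected about the replicon midpoint
      L <- config$replicon_len
      new_start <- L - genes$end + 1L
      new_end <- L - genes$start + 1L
      genes$start <- new_start; genes$end <- new_end
      genes <- genes[order(genes$start), , drop = FALSE]
      seq <- reverse_complement(seq)
      sd_pos <- L - (sd_pos + 5L) + 1L
      prom_pos <- L - (prom_pos + 28L) + 1L
    }
    source_kind <- if (t == "hsdRSMS") "plasmid" else "chromosome"
    rec <- genome_record(replicon_id, seq, genes,
                         topology = if (source_kind == "plasmid") "circular"
                                    else "linear",
                         source_kind = source_kind)
    records[[replicon_id]] <- rec
    truth$operons[[replicon_id]] <- list(
      topology = if (t == "typeIII") "typeIII_mod_res"
                 else if (t == "typeIV") "typeIV_pair"
                 else if (t == "IIG") "single"
                 else t,
      roles = roles, starts = genes$start, ends = genes$end,
      strand = config$strand,
      overlap_bp = if (t == "hsdRSMS") config$overlap
                   else if (t == "typeIV") 4L else 0L,
      sd_positions = sd_pos, promoter_positions = prom_pos)
  }
  list(records = records, truth = truth)
}

#' Simulate an SMRT motif report for a genome
#'
#' `n_genome` is the strand-specific motif occurrence count (palindromic
#' motifs have one methylatable site per strand, so duplex sites count
#' twice); `n_detected ~ Binomial(n_genome, true_fraction)` models per-site
#' Bernoulli detection; per-site coverage is Poisson(`mean_cov`) and the
#' per-site score is a deterministic increasing function of coverage
#' (`round(30 + 1.35 * coverage)`) — enough to exercise report parsing and
#' the fraction statistic without modeling polymerase kinetics.
#'
#' @param genome A `GenomeRecord` or nucleotide string.
#' @param motif A `DegenerateMotif` or pattern string.
#' @param true_fraction True per-site modification probability.
#' @param mean_cov Mean per-site coverage.
#' @param seed Integer seed.
#' @param mod_type Modification chemistry for the report (default `"m6A"`).
#' @return List with `report` (one-row `motif_summary` `data.frame`) and
#'   `sites` (per-site calls, the detected subset, in [read_basemod_gff()]
#'   layout).
#' @export
simulate_motif_report <- function(genome, motif, true_fraction,
                                  mean_cov = 150, seed = 1L,
                                  mod_type = "m6A") {
  stopifnot(true_fraction >= 0, true_fraction <= 1)
  set.seed(seed)
  seqchr <- if (inherits(genome, "GenomeRecord")) genome$sequence else genome
  seqid <- if (inherits(genome, "GenomeRecord")) genome$replicon_id else "seq"
  circular <- inherits(genome, "GenomeRecord") &&
    genome$topology == "circular"
  hits <- scan_motif(seqchr, motif, circular = circular)
  pat <- .motif_pattern(motif)
  if (is_palindromic(pat) && nrow(hits)) {
    hits <- rbind(hits,
                  data.frame(position = hits$position, strand = "-",
                             stringsAsFactors = FALSE))
  }
  n_genome <- nrow(hits)
  if (n_genome == 0L)
    stop("motif has no genomic occurrence; nothing to simulate")
  n_detected <- stats::rbinom(1L, n_genome, true_fraction)
  coverage <- stats::rpois(n_genome, mean_cov)
  score <- round(30 + 1.35 * coverage)
  detected <- sort(sample.int(n_genome, n_detected))
  sites <- if (n_detected == 0L) data.frame(
    seqid = character(0), position = integer(0), strand = character(0),
    type = character(0), score = numeric(0), coverage = numeric(0),
    context = character(0), ipd_ratio = numeric(0),
    stringsAsFactors = FALSE)
  else data.frame(
    seqid = seqid, position = hits$position[detected],
    strand = hits$strand[detected], type = mod_type,
    score = score[detected], coverage = coverage[detected],
    context = vapply(hits$position[detected], function(p)
      substr(seqchr, max(1L, p - 5L), min(nchar(seqchr), p + 5L)),
      character(1)),
    ipd_ratio = round(2 + 3 * stats::runif(n_detected), 2),
    stringsAsFactors = FALSE)
  report <- data.frame(
    motif_string = pat,
    center_pos = if (inherits(motif, "DegenerateMotif") &&
                     !is.na(motif$modified_pos)) motif$modified_pos else 1L,
    mod_type = mod_type,
    fraction = modification_fraction(n_detected, n_genome, 2L),
    n_detected = n_detected, n_genome = n_genome,
    mean_score = if (n_detected) round(mean(score[detected])) else 0,
    mean_cov = round(mean(coverage), 1),
    stringsAsFactors = FALSE)
  class(report) <- c("motif_summary", "data.frame")
  list(report = report, sites = sites)
}

#' Default configuration for the HsdS alignment cohort generator
#'
#' @param n_seq Number of aligned sequences.
#' @param type `"long"` (two variable TRD blocks) or `"short"` (fully
#'   conserved).
#' @param cr_lens Lengths of the N-terminal, central and C-terminal
#'   conserved regions (columns).
#' @param trd_len TRD block length (columns).
#' @param cr_rate Per-residue mutation rate inside conserved regions.
#' @param repeat_unit Repeat planted twice in the central region.
#' @param repeat_gap Residues between the two planted copies.
#' @return Config list for [generate_hsds_cohort()].
#' @export
hsds_config <- function(n_seq = 11L, type = c("long", "short"),
                        cr_lens = c(60L, 90L, 40L), trd_len = 150L,
                        cr_rate = 0.02, repeat_unit = "LEEQK",
                        repeat_gap = 3L) {
  list(n_seq = as.integer(n_seq), type = match.arg(type),
       cr_lens = as.integer(cr_lens), trd_len = as.integer(trd_len),
       cr_rate = cr_rate, repeat_unit = repeat_unit,
       repeat_gap = as.integer(repeat_gap))
}

#' Generate a synthetic HsdS alignment cohort
#'
#' Long-subunit cohorts consist of three conserved regions (mutated from a
#' common consensus at a low rate) flanking two variable blocks sampled
#' independently per sequence; the central region carries two planted copies
#' of `repeat_unit` separated by `repeat_gap` residues. Short-subunit
#' cohorts are conserved along their entire length. Gap-free, so rows are
#' already aligned.
#'
#' @param config From [hsds_config()].
#' @param seed Integer seed.
#' @return List with `alignment` (named character vector) and `truth`
#'   (planted segment boundaries, repeat unit/positions within the central
#'   region consensus).
#' @export
generate_hsds_cohort <- function(config = hsds_config(), seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cr <- lapply(config$cr_lens, .random_aa)
  # plant the repeat pair in the central conserved region
  unit <- config$repeat_unit
  k <- nchar(unit)
  span <- 2L * k + config$repeat_gap
  stopifnot(config$cr_lens[2] >= span)
  rep_at <- (config$cr_lens[2] - span) %/% 2L + 1L
  ccr <- cr[[2]]
  substr(ccr, rep_at, rep_at + k - 1L) <- unit
  substr(ccr, rep_at + k + config$repeat_gap,
         rep_at + span - 1L) <- unit
  cr[[2]] <- ccr
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(ch)) < rate
    ch[hit] <- sample(aa, sum(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  # the planted repeat pair is a conserved feature: re-write it after mutation
  mutate_ccr <- function() {
    s <- mutate(cr[[2]], config$cr_rate)
    substr(s, rep_at, rep_at + k - 1L) <- unit
    substr(s, rep_at + k + config$repeat_gap, rep_at + span - 1L) <- unit
    s
  }
  rows <- vapply(seq_len(config$n_seq), function(i) {
    if (config$type == "short") {
      paste0(mutate(cr[[1]], config$cr_rate), mutate_ccr(),
             mutate(cr[[3]], config$cr_rate))
    } else {
      paste0(mutate(cr[[1]], config$cr_rate),
             .random_aa(config$trd_len),
             mutate_ccr(),
             .random_aa(config$trd_len),
             mutate(cr[[3]], config$cr_rate))
    }
  }, character(1))
  names(rows) <- sprintf("hsdS_%s_%02d", config$type, seq_len(config$n_seq))
  truth <- list(seed = seed, type = config$type)
  if (config$type == "long") {
    b <- cumsum(c(config$cr_lens[1], config$trd_len, config$cr_lens[2],
                  config$trd_len, config$cr_lens[3]))
    truth$segments <- data.frame(
      label = c("N-CR", "TRD1", "cCR", "TRD2", "C-CR"),
      start_col = c(1L, utils::head(b, -1L) + 1L), end_col = b,
      stringsAsFactors = FALSE)
    truth$n_trd <- 2L
  } else {
    truth$segments <- data.frame(label = "CR", start_col = 1L,
                                 end_col = sum(config$cr_lens),
                                 stringsAsFactors = FALSE)
    truth$n_trd <- 0L
  }
  truth$repeat_unit <- unit
  truth$repeat_gap <- config$repeat_gap
  truth$repeat_pos_ccr <- rep_at          # within the central region
  list(alignment = rows, truth = truth)
}

#' Plant concrete motif instances into a sequence
#'
#' Writes `n` concretized copies of a degenerate motif (each degenerate
#' position sampled uniformly from its base set) at non-overlapping random
#' positions, emulating a genome with a planted recognition motif at a known
#' minimum occurrence count (background occurrences may add to it).
#'
#' @param sequence Nucleotide string.
#' @param motif A `DegenerateMotif` or pattern string.
#' @param n Number of instances to plant.
#' @param seed Integer seed.
#' @return List with `sequence` (modified) and `positions` (planted starts).
#' @export
plant_motif_sites <- function(sequence, motif, n, seed = 1L) {
  set.seed(seed)
  pat <- .motif_pattern(motif)
  k <- nchar(pat)
  L <- nchar(sequence)
  stopifnot(n * (k + 1L) < L)
  # lay out non-overlapping slots
  slots <- seq(1L, L - k, by = k + 1L)
  if (length(slots) < n) stop("sequence too short to plant ", n, " sites")
  starts <- sort(sample(slots, n))
  codes <- strsplit(pat, "")[[1]]
  for (s in starts) {
    inst <- paste(vapply(codes, function(c) {
      b <- iupac_bases(c)
      if (length(b) == 1L) b else sample(b, 1L)
    }, character(1)), collapse = "")
    substr(sequence, s, s + k - 1L) <- inst
  }
  list(sequence = sequence, positions = starts)
}

#' Generate a cohort of synthetic reference families and mutated members
#'
#' One prototype protein per family plus mutated copies at a planted
#' within-family identity; used to exercise family classification and tree
#' grouping.
#'
#' @param families Character vector of family ids.
#' @param n_members Mutated copies per family.
#' @param prot_len Protein length (aa).
#' @param member_identity Planted within-family identity fraction
#'   (e.g. 0.85).
#' @param seed Integer seed.
#' @return List with `references` (named prototypes), `members` (named
#'   mutated sequences), `labels` (member -> family).
#' @export
generate_family_cohort <- function(families = c("IA", "IB", "IC", "ID", "IE"),
                                   n_members = 2L, prot_len = 300L,
                                   member_identity = 0.85, seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  refs <- vapply(families, function(f) .random_aa(prot_len), character(1))
  members <- character(0)
  labels <- character(0)
  for (f in families) {
    for (m in seq_len(n_members)) {
      ch <- strsplit(refs[[f]], "")[[1]]
      hit <- stats::runif(prot_len) > member_identity
      # substitute with a different residue so identity is controlled
      ch[hit] <- vapply(which(hit), function(i)
        sample(setdiff(aa, ch[i]), 1L), character(1))
      nm <- sprintf("%s_member%d", f, m)
      members[nm] <- paste(ch, collapse = "")
      labels[nm] <- f
    }
  }
  list(references = refs, members = members, labels = labels)
}

#' Generate a cross-strain cohort with motif/gene-family linkage
#'
#' Plants gene families with chosen presence patterns across strains; each
#' linked motif's presence vector mirrors its family's pattern except at
#' configured corruption positions. Family members are near-identical
#' mutated copies of a family prototype, so presence-matrix clustering
#' reconstitutes the planted families.
#'
#' @param n_strains Number of strains.
#' @param n_families Number of linked gene families (each gets one motif).
#' @param presence Optional logical matrix (families x strains); random
#'   patterns (each family present in 1..n-1 strains) when `NULL`.
#' @param corrupt `data.frame` with columns `family` (index) and `strain`
#'   (index): strains where the motif vector is flipped relative to the
#'   family pattern.
#' @param prot_len Prototype protein length.
#' @param seed Integer seed.
#' @return List with `inventories` (strain -> `data.frame(locus_tag,
#'   aa_seq)`), `motif_presence` (list: motif id -> logical vector),
#'   `truth` (planted presence matrix and linkage).
#' @export
generate_cohort_with_motif_linkage <- function(n_strains = 4L,
                                               n_families = 2L,
                                               presence = NULL,
                                               corrupt = NULL,
                                               prot_len = 120L, seed = 1L) {
  stopifnot(n_strains >= 2L)
  set.seed(seed)
  strains <- sprintf("strain%02d", seq_len(n_strains))
  if (is.null(presence)) {
    repeat {
      presence <- matrix(stats::runif(n_families * n_strains) < 0.5,
                         n_families, n_strains)
      # informative, distinct patterns
      if (all(rowSums(presence) >= 1) && all(rowSums(presence) < n_strains) &&
          !anyDuplicated(apply(presence, 1, paste, collapse = ""))) break
    }
  }
  dimnames(presence) <- list(sprintf("plantedfam%d", seq_len(n_families)),
                             strains)
  protos <- vapply(seq_len(n_families), function(f) .random_aa(prot_len),
                   character(1))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  inventories <- lapply(seq_len(n_strains), function(s) {
    fams <- which(presence[, s])
    if (!length(fams))
      return(data.frame(locus_tag = character(0), aa_seq = character(0),
                        stringsAsFactors = FALSE))
    data.frame(
      locus_tag = sprintf("S%02d_fam%d", s, fams),
      aa_seq = vapply(fams, function(f) {
        ch <- strsplit(protos[f], "")[[1]]
        hit <- stats::runif(prot_len) < 0.03   # ~97% identity to prototype
        ch[hit] <- sample(aa, sum(hit), replace = TRUE)
        paste(ch, collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE)
  })
  names(inventories) <- strains
  motif_presence <- lapply(seq_len(n_families), function(f) {
    v <- presence[f, ]
    if (!is.null(corrupt)) {
      rows <- corrupt[corrupt$family == f, , drop = FALSE]
      v[rows$strain] <- !v[rows$strain]
    }
    v
  })
  names(motif_presence) <- sprintf("motif%d", seq_len(n_families))
  list(inventories = inventories, motif_presence = motif_presence,
       truth = list(seed = seed, presence = presence,
                    linkage = stats::setNames(rownames(presence),
                                              names(motif_presence))))
}
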
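# Classification of annotated genes into RM roles, operon reconstruction and
# topology labeling, regulatory-signal detection, per-strain completeness.

#' Default classification rule set
#'
#' Ordered keyword rules (first match wins) on annotation text, refined by
#' length rules, plus role-specific completeness length floors. The rules
#' reproduce standard annotation vocabularies for staphylococcal RM genes:
#' hsd subunits by "subunit S/M/R", methylation-dependent (type IV)
#' endonucleases by DUF3578/McrB/McrC tags, fused single-polypeptide
#' methyltransferase-endonucleases (type IIG) vs type III res genes by gene
#' length (IIG genes run well above 4 kb, type III res genes 2.7-3 kb and
#' sit next to a mod methyltransferase).
#'
#' @param max_gap Maximum intergenic gap (nt) within an operon run.
#' @param sd_mismatch Mismatch allowance for Shine-Dalgarno detection.
#' @return A list of configuration values used across the inventory stage.
#' @export
rm_rules <- function(max_gap = 200L, sd_mismatch = 1L) {
  list(
    max_gap = max_gap,
    sd_mismatch = sd_mismatch,
    iig_min_len = 4000L,
    # completeness floors: below the smallest complete instance of each role,
    # above every truncated one
    length_floors = c(hsdR = 1800L, hsdM = 1200L, hsdS = 450L,
                      fused_IIG = 4000L),
    promoter_m35_mismatch = 2L,
    promoter_m10_mismatch = 1L,
    promoter_spacer = c(16L, 19L)
  )
}

.ROLE_CLASS <- c(hsdR = "I", hsdM = "I", hsdS = "I",
                 mtase_II = "II", rease_II = "II", cytosine_mtase = "II",
                 fused_IIG = "IIG", mod_III = "III", res_III = "III",
                 mcrB_like = "IV", mcrC_like = "IV", unknown = "none")

#' Classify a gene into an RM role
#'
#' Ordered keyword rules on the product annotation, refined by length rules
#' (fused type IIG enzymes vs type III res genes) and optional local context
#' (`adjacent_mtase`: a site-specific methyltransferase within the operon
#' gap, which demotes a long helicase-like gene to a type III res call).
#' Falls through to role `"unknown"`; `evidence` records every rule fired;
#' `truncated` is set when the gene is below its role's completeness floor.
#'
#' @param product Annotation text (may be empty).
#' @param nt_len Gene length in nucleotides.
#' @param adjacent_mtase Is a site-specific/adenine methyltransferase
#'   annotated adjacent to this gene? (used only for helicase-like genes).
#' @param rules Rule set from [rm_rules()].
#' @return List of class `RMGeneCall` with `role`, `rm_class`, `evidence`,
#'   `truncated`.
#' @export
classify_rm_gene <- function(product, nt_len, adjacent_mtase = FALSE,
                             rules = rm_rules()) {
  p <- tolower(product %||% "")
  evidence <- character(0)
  role <- "unknown"
  hit <- function(role_, why) { role <<- role_; evidence <<- c(evidence, why) }

  if (grepl("subunit s", p) || grepl("specificity", p)) {
    hit("hsdS", "keyword: subunit S/specificity")
  } else if (grepl("subunit m", p) ||
             (grepl("type i ", paste0(p, " ")) && grepl("modification", p))) {
    hit("hsdM", "keyword: subunit M / type I modification")
  } else if (grepl("subunit r", p)) {
    hit("hsdR", "keyword: subunit R")
  } else if (grepl("duf3578", p) || grepl("mcrb", p)) {
    hit("mcrB_like", "keyword: DUF3578/McrB")
  } else if (grepl("mcrc", p)) {
    hit("mcrC_like", "keyword: McrC")
  } else if (grepl("helicase", p)) {
    if (!is.na(nt_len) && nt_len >= rules$iig_min_len && !adjacent_mtase) {
      hit("fused_IIG", sprintf("keyword: helicase; length %d >= %d, no adjacent MTase",
                               nt_len, rules$iig_min_len))
    } else {
      hit("res_III", "keyword: helicase; below IIG length floor or adjacent MTase")
    }
  } else if (grepl("alwi", p) || grepl("llaji", p)) {
    hit("rease_II", "keyword: type II family tag (AlwI/LlaJI)")
  } else if (grepl("site-specific dna", p) && grepl("methyltransferase", p)) {
    hit("mod_III", "keyword: site-specific DNA methyltransferase")
  } else if (grepl("adenine", p) && grepl("methyltransferase", p)) {
    hit("mtase_II", "keyword: adenine methyltransferase")
  } else if (grepl("cytosine", p) && grepl("methyltransferase", p) ||
             grepl("\\(c5\\)", p)) {
    hit("cytosine_mtase", "keyword: cytosine methyltransferase")
  } else if (grepl("methyltransferase", p)) {
    hit("mtase_II", "keyword: methyltransferase (generic)")
  } else if (grepl("restriction endonuclease", p)) {
    hit("res_III", "keyword: restriction endonuclease (no family tag)")
  } else if (grepl("atpase", p)) {
    hit("rease_II", "keyword: restriction-associated ATPase")
  }

  floor <- rules$length_floors[role]
  truncated <- !is.na(floor) && !is.na(nt_len) && nt_len < floor
  if (truncated)
    evidence <- c(evidence, sprintf("length %d below %s floor %d",
                                    nt_len, role, floor))
  structure(list(role = role, rm_class = unname(.ROLE_CLASS[role]),
                 evidence = evidence, truncated = truncated,
                 product = product, nt_len = nt_len),
            class = "RMGeneCall")
}

#' Classify all genes of a gene table
#'
#' Vectorized wrapper around [classify_rm_gene()]; adjacency of a
#' site-specific methyltransferase is computed from gene order and
#' `rules$max_gap` so that the IIG/type III length rule sees its context.
#'
#' @param genes Gene table (`locus_tag, start, end, strand, product, nt_len`).
#' @param rules Rule set from [rm_rules()].
#' @return The gene table with `role`, `rm_class`, `truncated`, `evidence`
#'   columns appended.
#' @export
classify_gene_table <- function(genes, rules = rm_rules()) {
  n <- nrow(genes)
  if (!n) {
    genes$role <- character(0); genes$rm_class <- character(0)
    genes$truncated <- logical(0); genes$evidence <- character(0)
    return(genes)
  }
  ord <- order(genes$start)
  genes <- genes[ord, , drop = FALSE]
  is_mtase <- grepl("methyltransferase", tolower(genes$product))
  adj <- vapply(seq_len(n), function(i) {
    prev_ok <- i > 1L && is_mtase[i - 1L] &&
      (genes$start[i] - genes$end[i - 1L] - 1L) <= rules$max_gap
    nxt_ok <- i < n && is_mtase[i + 1L] &&
      (genes$start[i + 1L] - genes$end[i] - 1L) <= rules$max_gap
    prev_ok || nxt_ok
  }, logical(1))
  calls <- lapply(seq_len(n), function(i)
    classify_rm_gene(genes$product[i], genes$nt_len[i], adj[i], rules))
  genes$role <- vapply(calls, `[[`, character(1), "role")
  genes$rm_class <- vapply(calls, `[[`, character(1), "rm_class")
  genes$truncated <- vapply(calls, `[[`, logical(1), "truncated")
  genes$evidence <- vapply(calls, function(x)
    paste(x$evidence, collapse = "; "), character(1))
  genes
}

#' Overlap between two neighboring genes
#'
#' `max(0, end(a) - start(b) + 1)` for `a` preceding `b` in genomic order on
#' the same replicon; used to detect translational coupling such as the 8 bp
#' overlap between the methyltransferase and the downstream long specificity
#' gene in hsdRSMS operons.
#'
#' @param a,b Single-row gene records (lists or data.frame rows with
#'   `start`, `end`, and optionally `replicon_id`).
#' @return Integer overlap in bp (>= 0).
#' @export
detect_overlap <- function(a, b) {
  if (!is.null(a$replicon_id) && !is.null(b$replicon_id) &&
      !identical(a$replicon_id, b$replicon_id))
    stop("genes on different replicons")
  if (a$start > b$start) stop("a must precede b in genomic order")
  max(0L, as.integer(a$end) - as.integer(b$start) + 1L)
}

#' Reconstruct RM operons from classified genes
#'
#' Builds maximal runs of RM-role genes on the same strand with intergenic
#' gaps at most `max_gap`, normalizes the gene order to transcription
#' orientation, and matches the role sequence against known topologies:
#' `R,S,M,S -> hsdRSMS`; `M,S,R -> hsdMSR`; `R,S,M -> hsdRSM`;
#' `mod+res -> typeIII_mod_res`; `mcrB+mcrC -> typeIV_pair`;
#' `mtase_II+rease_II -> typeII_pair`; anything else is `single`/`partial`.
#' Coordinate overlaps between neighbors are recorded.
#'
#' @param genes Classified gene table ([classify_gene_table()]) for one
#'   replicon, with a `replicon_id` attribute or column.
#' @param replicon_id Replicon name (defaults to `genes$replicon_id[1]`).
#' @param rules Rule set from [rm_rules()].
#' @return List of `Operon` objects: each has `replicon_id`, `genes`
#'   (transcription order), `strand`, `topology`, `overlaps`, `complete`.
#' @export
reconstruct_operons <- function(genes, replicon_id = NULL, rules = rm_rules()) {
  if (is.null(replicon_id))
    replicon_id <- if ("replicon_id" %in% names(genes) && nrow(genes))
      genes$replicon_id[1] else "replicon"
  rm_genes <- genes[genes$role != "unknown", , drop = FALSE]
  nostrand <- rm_genes$strand %in% c(".", "")
  if (any(nostrand)) {
    warning("gene(s) without strand excluded from operon runs: ",
            paste(rm_genes$locus_tag[nostrand], collapse = ", "))
    rm_genes <- rm_genes[!nostrand, , drop = FALSE]
  }
  if (!nrow(rm_genes)) return(list())
  rm_genes <- rm_genes[order(rm_genes$start), , drop = FALSE]
  n <- nrow(rm_genes)
  new_run <- c(TRUE, vapply(seq_len(n - 1L), function(i) {
    gap <- rm_genes$start[i + 1L] - rm_genes$end[i] - 1L
    gap > rules$max_gap || rm_genes$strand[i + 1L] != rm_genes$strand[i]
  }, logical(1)))
  run_id <- cumsum(new_run)
  lapply(split(rm_genes, run_id), function(run)
    .build_operon(run, replicon_id))
}

.ROLE_SYMBOL <- c(hsdR = "R", hsdS = "S", hsdM = "M",
                  mod_III = "mod", res_III = "res",
                  mcrB_like = "mcrB", mcrC_like = "mcrC",
                  mtase_II = "mtase", rease_II = "rease",
                  cytosine_mtase = "mtase", fused_IIG = "IIG")

.build_operon <- function(run, replicon_id) {
  strand <- run$strand[1]
  tx <- if (strand == "-") run[rev(seq_len(nrow(run))), , drop = FALSE] else run
  roles <- tx$role
  sym <- unname(.ROLE_SYMBOL[roles])
  sig <- paste(sym, collapse = ",")
  topology <-
    if (sig == "R,S,M,S") "hsdRSMS"
    else if (sig == "M,S,R") "hsdMSR"
    else if (sig == "R,S,M") "hsdRSM"
    else if (sig %in% c("mod,res", "res,mod")) "typeIII_mod_res"
    else if (sig %in% c("mcrB,mcrC", "mcrC,mcrB")) "typeIV_pair"
    else if (sig %in% c("mtase,rease", "rease,mtase")) "typeII_pair"
    else if (nrow(run) == 1L) "single"
    else "partial"
  # overlaps computed in genomic order
  overlaps <- NULL
  if (nrow(run) > 1L) {
    ov <- vapply(seq_len(nrow(run) - 1L), function(i)
      as.integer(max(0, run$end[i] - run$start[i + 1L] + 1)), integer(1))
    keep <- ov > 0L
    if (any(keep))
      overlaps <- data.frame(gene_i = run$locus_tag[which(keep)],
                             gene_j = run$locus_tag[which(keep) + 1L],
                             overlap_bp = ov[keep], stringsAsFactors = FALSE)
  }
  complete <- .operon_complete(tx, topology)
  structure(list(replicon_id = replicon_id, genes = tx, strand = strand,
                 topology = topology, overlaps = overlaps,
                 regulatory = NULL, complete = complete),
            class = "Operon")
}

.operon_complete <- function(tx, topology) {
  ok <- function(role) any(tx$role == role & !tx$truncated)
  if (topology %in% c("hsdRSMS", "hsdMSR", "hsdRSM"))
    ok("hsdR") && ok("hsdM") && ok("hsdS")
  else if (topology == "typeIII_mod_res") ok("mod_III") && ok("res_III")
  else if (topology == "typeIV_pair") ok("mcrB_like") && ok("mcrC_like")
  else if (topology == "typeII_pair")
    any(tx$role %in% c("mtase_II", "cytosine_mtase") & !tx$truncated) &&
      ok("rease_II")
  else if (topology == "single" && tx$role[1] == "fused_IIG") !tx$truncated[1]
  else FALSE
}

#' @export
print.Operon <- function(x, ...) {
  cat("<Operon> ", x$replicon_id, " [", x$topology, "] strand ", x$strand,
      ": ", paste(x$genes$role, collapse = "-"),
      if (x$complete) " (complete)" else " (incomplete)", "\n", sep = "")
  invisible(x)
}

#' Find a Shine-Dalgarno site upstream of a start codon
#'
#' Searches the upstream window (given in transcription orientation, ending
#' immediately before the start codon) for the best `AGGAGG` match with at
#' most `max_mismatch` mismatches whose 3' end lies 4-16 nt upstream of the
#' start codon. Ties are broken toward the start codon.
#'
#' @param seq_upstream Upstream nucleotide string.
#' @param max_mismatch Mismatch allowance (default 1, i.e. >= 5 of 6 match).
#' @return `NULL`, or a list (`kind`, `position` of the match start within
#'   the window, `mismatches`, `dist_to_start`).
#' @export
find_shine_dalgarno <- function(seq_upstream, max_mismatch = 1L) {
  sd <- "AGGAGG"
  seq_upstream <- toupper(seq_upstream)
  n <- nchar(seq_upstream)
  if (n < nchar(sd)) return(NULL)
  best <- NULL
  for (p in seq_len(n - nchar(sd) + 1L)) {
    dist <- n - (p + nchar(sd) - 1L)      # 3' end to start codon
    if (dist < 4L || dist > 16L) next
    mm <- .count_mismatches(substr(seq_upstream, p, p + nchar(sd) - 1L), sd)
    if (mm > max_mismatch) next
    if (is.null(best) || mm < best$mismatches ||
        (mm == best$mismatches && dist < best$dist_to_start))
      best <- list(kind = "shine_dalgarno", position = p, mismatches = mm,
                   dist_to_start = dist)
  }
  best
}

#' Find a sigma-70 promoter upstream of a gene
#'
#' Best `TTGACA` (-35, at most `m35` mismatches) / spacer 16-19 nt /
#' `TATAAT` (-10, at most `m10` mismatches) pair in an upstream window,
#' scored by total mismatches; ties resolved toward the gene start with a
#' warning.
#'
#' @param seq_upstream Upstream window (transcription orientation, at most
#'   ~300 nt; longer input is searched in full).
#' @param m35,m10 Mismatch allowances for the -35 and -10 boxes.
#' @param spacer_range Allowed spacer lengths (inclusive).
#' @return `NULL`, or a list (`kind`, `position` of the -35 box,
#'   `mismatches` total, `spacer`).
#' @export
find_sigma70_promoter <- function(seq_upstream, m35 = 2L, m10 = 1L,
                                  spacer_range = c(16L, 19L)) {
  b35 <- "TTGACA"; b10 <- "TATAAT"
  seq_upstream <- toupper(seq_upstream)
  n <- nchar(seq_upstream)
  if (n < 12L + spacer_range[1]) return(NULL)
  best <- NULL; tie <- FALSE
  for (p in seq_len(n)) {
    if (p + 5L > n) break
    mm35 <- .count_mismatches(substr(seq_upstream, p, p + 5L), b35)
    if (mm35 > m35) next
    for (sp in seq(spacer_range[1], spacer_range[2])) {
      q <- p + 6L + sp
      if (q + 5L > n) next
      mm10 <- .count_mismatches(substr(seq_upstream, q, q + 5L), b10)
      if (mm10 > m10) next
      score <- mm35 + mm10
      cand <- list(kind = "sigma70_promoter", position = p,
                   mismatches = score, spacer = sp, end10 = q + 5L)
      if (is.null(best) || score < best$mismatches) {
        best <- cand; tie <- FALSE
      } else if (score == best$mismatches) {
        if (cand$end10 > best$end10) { best <- cand; tie <- TRUE }
        else tie <- TRUE
      }
    }
  }
  if (!is.null(best) && tie)
    warning("multiple equal-score promoter candidates; reporting the one nearest the gene start")
  if (!is.null(best)) best$end10 <- NULL
  best
}

.count_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Per-strain RM system completeness
#'
#' A strain has a complete type I system iff some operon contains
#' non-truncated hsdR, hsdM and at least one non-truncated hsdS; a type IIG
#' system iff a non-truncated fused enzyme exists; type III iff a mod+res
#' pair; type IV iff an mcrB-like + mcrC-like pair.
#'
#' @param operons_per_strain Named list: strain -> list of `Operon`.
#' @return `data.frame` with one row per strain and logical/count summary
#'   columns (`complete_type_I`, `type_IIG`, `complete_type_III`,
#'   `complete_type_IV`, `n_operons`).
#' @export
call_completeness <- function(operons_per_strain) {
  rows <- lapply(names(operons_per_strain), function(strain) {
    ops <- operons_per_strain[[strain]]
    topo <- vapply(ops, `[[`, character(1), "topology")
    comp <- vapply(ops, `[[`, logical(1), "complete")
    has_iig <- any(vapply(ops, function(o)
      any(o$genes$role == "fused_IIG" & !o$genes$truncated), logical(1)))
    data.frame(
      strain = strain,
      complete_type_I = any(topo %in% c("hsdRSMS", "hsdMSR", "hsdRSM") & comp),
      type_IIG = has_iig,
      complete_type_III = any(topo == "typeIII_mod_res" & comp),
      complete_type_IV = any(topo == "typeIV_pair" & comp),
      n_operons = length(ops),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Amino-acid length of a CDS
#'
#' `nt_len / 3 - 1` (the stop codon is removed); a length not divisible by 3
#' is a frame error.
#'
#' @param nt_len CDS length in nucleotides (divisible by 3, >= 6).
#' @return Integer protein length in aa.
#' @examples
#' protein_length_from_cds(576)  # 191
#' @export
protein_length_from_cds <- function(nt_len) {
  nt_len <- as.integer(nt_len)
  if (any(nt_len < 6L)) stop("CDS shorter than two codons")
  if (any(nt_len %% 3L != 0L)) stop("frame error: nt_len not divisible by 3")
  nt_len %/% 3L - 1L
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
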
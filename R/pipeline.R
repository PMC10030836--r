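# End-to-end orchestration: strain inventory, family analysis, HsdS analysis.
# Every threshold that affects a verdict is echoed into the run log so runs
# are auditable; same inputs + config + seed give identical reports.

#' Run the strain RM inventory
#'
#' Two modes. Fixture mode (`fixture = TRUE`) classifies every row of the
#' packaged strain inventory from annotation text and length alone, groups
#' contiguous same-class rows per strain/replicon into systems, and tallies
#' per-strain completeness. Genome mode classifies the CDS of supplied
#' `GenomeRecord`s, reconstructs operons and labels topologies.
#'
#' @param genomes Named list: strain -> list of `GenomeRecord` (genome mode).
#' @param motif_reports Optional named list: strain -> `motif_summary`
#'   `data.frame`; motifs are carried into the report.
#' @param fixture Use the packaged strain-inventory fixture instead of
#'   genomes.
#' @param rules Rule set from [rm_rules()].
#' @param log Function receiving log lines (default collects silently).
#' @return List of class `rm_inventory_report`: `report` (per-gene table
#'   with computed role/class), `completeness` (per-strain summary),
#'   `summary` (tallies), `log`.
#' @export
run_inventory <- function(genomes = NULL, motif_reports = NULL,
                          fixture = FALSE, rules = rm_rules(),
                          log = NULL) {
  lines <- character(0)
  logf <- function(...) {
    msg <- sprintf(...)
    lines <<- c(lines, msg)
    if (!is.null(log)) log(msg)
  }
  logf("inventory: max_gap=%d iig_min_len=%d floors[hsdR=%d,hsdM=%d,hsdS=%d]",
       rules$max_gap, rules$iig_min_len, rules$length_floors["hsdR"],
       rules$length_floors["hsdM"], rules$length_floors["hsdS"])
  if (fixture) {
    fx <- load_table1_fixture()
    res <- classify_fixture(fx, rules)
    completeness <- fixture_completeness(res, rules)
    summary <- list(
      n_strains = length(unique(res$strain)),
      complete_type_I = sum(completeness$complete_type_I),
      type_IIG = sum(completeness$type_IIG),
      complete_type_III = sum(completeness$complete_type_III),
      complete_type_IV = sum(completeness$complete_type_IV))
  } else {
    if (is.null(genomes) || !length(genomes))
      stop("usage error: supply genomes or set fixture = TRUE")
    per_strain <- lapply(genomes, function(recs) {
      if (inherits(recs, "GenomeRecord")) recs <- list(recs)
      ops <- list()
      tabs <- list()
      for (rec in recs) {
        g <- classify_gene_table(rec$genes, rules)
        g$replicon_id <- rec$replicon_id
        g$location <- rec$source_kind
        tabs[[rec$replicon_id]] <- g
        ops <- c(ops, reconstruct_operons(g, rec$replicon_id, rules))
      }
      list(genes = do.call(rbind, tabs), operons = ops)
    })
    res <- do.call(rbind, lapply(names(per_strain), function(s) {
      g <- per_strain[[s]]$genes
      if (is.null(g) || !nrow(g)) return(NULL)
      cbind(strain = s, g)
    }))
    rownames(res) <- NULL
    completeness <- call_completeness(lapply(per_strain, `[[`, "operons"))
    summary <- list(
      n_strains = length(genomes),
      complete_type_I = sum(completeness$complete_type_I),
      type_IIG = sum(completeness$type_IIG),
      complete_type_III = sum(completeness$complete_type_III),
      complete_type_IV = sum(completeness$complete_type_IV),
      topologies = table(unlist(lapply(per_strain, function(x)
        vapply(x$operons, `[[`, character(1), "topology")))))
  }
  if (!is.null(motif_reports))
    summary$motifs <- lapply(motif_reports, function(r) r$motif_string)
  logf("inventory: %d strains, %d complete type I, %d type IIG",
       summary$n_strains, summary$complete_type_I, summary$type_IIG)
  structure(list(report = res, completeness = completeness,
                 summary = summary, log = lines),
            class = "rm_inventory_report")
}

#' Classify the packaged fixture rows
#'
#' Applies [classify_rm_gene()] to each row of the fixture inventory using
#' annotation text and length alone. Type III adjacency is resolved from
#' same-strain row adjacency in the table (mirroring gene adjacency in the
#' source genomes).
#'
#' @param fx Fixture `data.frame` from [load_table1_fixture()].
#' @param rules Rule set.
#' @return The fixture table with `role`, `computed_class`, `truncated`
#'   columns appended.
#' @export
classify_fixture <- function(fx, rules = rm_rules()) {
  n <- nrow(fx)
  is_mtase <- grepl("methyltransferase", tolower(fx$annotation))
  adj <- vapply(seq_len(n), function(i) {
    same <- function(j) j >= 1L && j <= n && fx$strain[j] == fx$strain[i] &&
      fx$location[j] == fx$location[i]
    (same(i - 1L) && is_mtase[i - 1L]) || (same(i + 1L) && is_mtase[i + 1L])
  }, logical(1))
  calls <- lapply(seq_len(n), function(i)
    classify_rm_gene(fx$annotation[i], fx$nt_len[i], adj[i], rules))
  fx$role <- vapply(calls, `[[`, character(1), "role")
  fx$computed_class <- vapply(calls, `[[`, character(1), "rm_class")
  fx$truncated <- vapply(calls, `[[`, logical(1), "truncated")
  fx
}

#' Per-strain completeness from classified fixture rows
#'
#' Treats each strain's rows on one replicon location as co-located systems:
#' complete type I needs non-truncated hsdR + hsdM + hsdS on one location;
#' IIG needs a non-truncated fused enzyme; type III a mod+res pair; type IV
#' an mcrB-like + mcrC-like pair.
#'
#' @param cls Output of [classify_fixture()].
#' @param rules Rule set.
#' @return Per-strain completeness `data.frame` (as [call_completeness()]).
#' @export
fixture_completeness <- function(cls, rules = rm_rules()) {
  rows <- lapply(unique(cls$strain), function(s) {
    sub <- cls[cls$strain == s, , drop = FALSE]
    by_loc <- split(sub, sub$location_raw)
    ok_in <- function(loc, role) any(loc$role == role & !loc$truncated)
    type1 <- any(vapply(by_loc, function(loc)
      ok_in(loc, "hsdR") && ok_in(loc, "hsdM") && ok_in(loc, "hsdS"),
      logical(1)))
    iig <- any(sub$role == "fused_IIG" & !sub$truncated)
    type3 <- any(vapply(by_loc, function(loc)
      ok_in(loc, "mod_III") && ok_in(loc, "res_III"), logical(1)))
    type4 <- any(vapply(by_loc, function(loc)
      ok_in(loc, "mcrB_like") && ok_in(loc, "mcrC_like"), logical(1)))
    data.frame(strain = s, complete_type_I = type1, type_IIG = iig,
               complete_type_III = type3, complete_type_IV = type4,
               n_operons = NA_integer_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the type I family analysis
#'
#' Computes the identity matrix of queries and references, one `FamilyCall`
#' per query, and a neighbor-joining tree on `1 - identity/100` distances.
#'
#' @param queries Named character vector of query protein sequences.
#' @param references Named character vector of family reference proteins.
#' @param families Named character vector: reference name -> family id
#'   (defaults to reference names).
#' @param member_threshold,novel_threshold Verdict thresholds.
#' @return List of class `rm_family_report`: `identity` (matrix), `calls`
#'   (list of `FamilyCall`), `tree` (`phylo`), `newick`, `log`.
#' @export
run_family_analysis <- function(queries, references, families = NULL,
                                member_threshold = 70, novel_threshold = 30) {
  stopifnot(length(queries) >= 1L, length(references) >= 1L)
  if (is.null(families))
    families <- stats::setNames(names(references), names(references))
  seqs <- c(queries, references)
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  idm <- identity_matrix(seqs)
  calls <- lapply(names(queries), function(q) {
    ids <- vapply(unique(families), function(f) {
      refs <- names(families)[families == f]
      max(idm[q, refs])
    }, numeric(1))
    classify_family(identities = ids, member_threshold = member_threshold,
                    novel_threshold = novel_threshold)
  })
  names(calls) <- names(queries)
  tree <- nj_tree(identity_to_distance(idm))
  log <- sprintf("families: member_threshold=%g novel_threshold=%g",
                 member_threshold, novel_threshold)
  structure(list(identity = idm, calls = calls, tree = tree,
                 newick = write_newick(tree), log = log),
            class = "rm_family_report")
}

#' Run the HsdS architecture analysis
#'
#' Conservation profile, CR/TRD segmentation and repeat detection for an
#' aligned specificity-subunit cohort.
#'
#' @param alignment Named character vector of aligned rows (or alignment
#'   file path, read with [read_alignment()]).
#' @param window Smoothing window (columns).
#' @param threshold Conservation threshold below which columns are variable.
#' @param min_len Minimum TRD length (columns).
#' @param repeat_max_gap Maximum gap between short-repeat copies (aa).
#' @return List of class `rm_hsds_report`: `profile`, `segments`, `repeats`
#'   (short repeats of the central region of the first ungapped row),
#'   `tandem_repeats`, `log`.
#' @export
run_hsds_analysis <- function(alignment, window = 9L, threshold = 0.5,
                              min_len = 50L, repeat_max_gap = 5L) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment))
    alignment <- read_alignment(alignment)
  if (length(alignment) < 2L) stop("alignment needs >= 2 rows")
  prof <- conservation_profile(alignment, window = window)
  segs <- segment_trds(prof, threshold = threshold, min_len = min_len)
  row1 <- gsub("-", "", alignment[[1]])
  ccr <- segs[segs$label %in% c("cCR", "CR"), , drop = FALSE]
  rep_seq <- if (nrow(ccr)) substr(row1, ccr$start_col[1], ccr$end_col[1])
             else row1
  structure(list(profile = prof, segments = segs,
                 repeats = find_short_repeats(rep_seq,
                                              max_gap = repeat_max_gap),
                 tandem_repeats = find_tandem_tetrapeptide_repeats(rep_seq),
                 log = sprintf(
                   "hsds: window=%d threshold=%g min_len=%d repeat_max_gap=%d",
                   window, threshold, min_len, repeat_max_gap)),
            class = "rm_hsds_report")
}
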
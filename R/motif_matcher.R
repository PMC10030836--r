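# Assignment of observed methylation motifs to candidate modification genes:
# cross-strain presence/absence concordance and known-motif table lookup.

#' Build a gene-family presence/absence matrix across strains
#'
#' Pools the modification-capable genes of all strains, clusters them into
#' families by single-linkage at `clustering_identity` percent identity
#' (orthologous systems are matched across strains, not locus tags), and
#' marks family presence per strain.
#'
#' @param inventories Named list: strain -> `data.frame` with columns
#'   `locus_tag` and `aa_seq` (amino-acid sequences of candidate genes).
#' @param clustering_identity Single-linkage identity threshold (default 90).
#' @return List of class `PresenceMatrix`: `matrix` (families x strains,
#'   logical), `families` (named list of member locus tags), `strains`.
#' @export
build_presence_matrix <- function(inventories, clustering_identity = 90) {
  stopifnot(length(inventories) >= 1L, !is.null(names(inventories)))
  strains <- names(inventories)
  pool <- do.call(rbind, lapply(strains, function(s) {
    inv <- inventories[[s]]
    if (!nrow(inv)) return(NULL)
    data.frame(strain = s, locus_tag = inv$locus_tag, aa_seq = inv$aa_seq,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pool) || !nrow(pool)) {
    m <- matrix(FALSE, 0, length(strains),
                dimnames = list(NULL, strains))
    return(structure(list(matrix = m, families = list(), strains = strains),
                     class = "PresenceMatrix"))
  }
  n <- nrow(pool)
  membership <- if (n == 1L) 1L else {
    idm <- matrix(100, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      idm[i, j] <- idm[j, i] <- percent_identity(pool$aa_seq[i], pool$aa_seq[j])
    hc <- stats::hclust(stats::as.dist(100 - idm), method = "single")
    stats::cutree(hc, h = 100 - clustering_identity)
  }
  fam_ids <- sort(unique(membership))
  fams <- lapply(fam_ids, function(f) pool$locus_tag[membership == f])
  names(fams) <- paste0("fam", fam_ids)
  m <- matrix(unlist(lapply(fam_ids, function(f)
    strains %in% pool$strain[membership == f])),
    nrow = length(fam_ids), byrow = TRUE,
    dimnames = list(names(fams), strains))
  structure(list(matrix = m, families = fams, strains = strains),
            class = "PresenceMatrix")
}

#' @export
print.PresenceMatrix <- function(x, ...) {
  cat("<PresenceMatrix> ", nrow(x$matrix), " families x ",
      length(x$strains), " strains\n", sep = "")
  invisible(x)
}

#' Assign a motif to gene families by cross-strain concordance
#'
#' Scores each gene family by the fraction of strains where family presence
#' equals motif presence; candidates are ranked by score, then family size.
#' The verdict is `unique` when exactly one family reaches perfect
#' concordance (score 1.0), `unassigned` when no family scores at least
#' `min_score`, and `ambiguous` otherwise (including ties — never an
#' arbitrary choice). The default `min_score` of 1 reflects that assignments
#' are trusted only when a single candidate co-occurs perfectly.
#'
#' @param pm A `PresenceMatrix`.
#' @param motif_presence Logical vector over strains (same order as
#'   `pm$strains`) marking where the motif was observed.
#' @param min_score Minimum concordance for an assignment (default 1.0).
#' @return List of class `MotifAssignment`: `candidates` (`data.frame`
#'   family/score/size, ranked), `verdict`.
#' @export
concordance_match <- function(pm, motif_presence, min_score = 1.0) {
  stopifnot(inherits(pm, "PresenceMatrix"))
  motif_presence <- as.logical(motif_presence)
  if (length(motif_presence) != length(pm$strains))
    stop("motif presence vector length != number of strains")
  if (!any(motif_presence))
    warning("motif absent from every strain; absent families score 1.0")
  if (!nrow(pm$matrix)) {
    return(structure(list(candidates = data.frame(family = character(0),
                                                  score = numeric(0),
                                                  size = integer(0)),
                          verdict = "unassigned"),
                     class = "MotifAssignment"))
  }
  score <- apply(pm$matrix, 1, function(fam) mean(fam == motif_presence))
  size <- vapply(pm$families, length, integer(1))
  ord <- order(-score, -size)
  cand <- data.frame(family = rownames(pm$matrix)[ord], score = score[ord],
                     size = size[ord], stringsAsFactors = FALSE,
                     row.names = NULL)
  top <- cand$score[1]
  verdict <- if (top < min_score) "unassigned"
             else if (sum(abs(cand$score - top) < 1e-12) > 1L) "ambiguous"
             else if (abs(top - 1.0) < 1e-12) "unique"
             else "ambiguous"
  structure(list(candidates = cand, verdict = verdict),
            class = "MotifAssignment")
}

#' @export
print.MotifAssignment <- function(x, ...) {
  cat("<MotifAssignment> ", x$verdict, sep = "")
  if (nrow(x$candidates))
    cat(": top ", x$candidates$family[1], " (score ",
        sprintf("%.3f", x$candidates$score[1]), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Look a motif up in a known-motif reference table
#'
#' Exact-string matches of the pattern and of its reverse complement against
#' a user-supplied table of known recognition motifs (e.g. a REBASE export);
#' reverse-complement hits are flagged.
#'
#' @param m A `DegenerateMotif` or IUPAC pattern string.
#' @param table `data.frame` with columns `motif`, `name`, `rm_type`, or a
#'   path to a TSV with those columns.
#' @return `data.frame` of hits (`motif`, `name`, `rm_type`, `rc`).
#' @export
reference_lookup <- function(m, table) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.table(table, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  stopifnot(all(c("motif", "name", "rm_type") %in% names(table)))
  pat <- .motif_pattern(m)
  rc <- reverse_complement(pat)
  fwd <- toupper(table$motif) == pat
  rev_ <- toupper(table$motif) == rc & !fwd
  out <- rbind(
    if (any(fwd)) cbind(table[fwd, c("motif", "name", "rm_type")], rc = FALSE),
    if (any(rev_)) cbind(table[rev_, c("motif", "name", "rm_type")], rc = TRUE))
  if (is.null(out))
    out <- data.frame(motif = character(0), name = character(0),
                      rm_type = character(0), rc = logical(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
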
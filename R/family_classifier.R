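# Type I family classification: global-alignment percent identity against
# family reference proteins (IA-IE), membership verdicts, neighbor-joining
# trees of hsdM/hsdR sequences.

#' Global-alignment percent identity of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap open 10,
#' gap extend 1, end gaps penalized). Identity is `100 * matches / alignment
#' length` with gapped columns included in the denominator — the conservative,
#' symmetric convention, stated explicitly because "percent identity" is
#' ambiguous across tools.
#'
#' @param a,b Amino-acid strings over the 20-letter alphabet (`X` allowed).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' percent_identity("ACDEF", "ACDFF")  # 80
#' percent_identity("ACDEF", "ACD")    # 60 (end gaps counted)
#' @export
percent_identity <- function(a, b, gap_opening = 10, gap_extension = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  # canonical argument order: optimal-score alignments are not unique, and
  # different tie-breaks for (a,b) vs (b,a) could yield slightly different
  # identities; fixing the order makes the statistic exactly symmetric
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pa == pb & pa != "-") / length(pa)
}

#' Pairwise identity matrix
#'
#' Symmetric matrix of global-alignment percent identities (diagonal 100).
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param ... Passed to [percent_identity()].
#' @return Numeric matrix with sequence names as dimnames.
#' @export
identity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- percent_identity(seqs[[i]], seqs[[j]], ...)
  }
  m
}

#' Classify a type I protein into a family
#'
#' Computes identity against one reference protein per family and applies the
#' consensus thresholds for type I families: members of the same family share
#' over ~70% identity, members of different families under ~30%. The closest
#' family is the argmax; the verdict is `member` (>= `member_threshold`),
#' `novel` (all identities < `novel_threshold`) or `borderline` otherwise —
#' the borderline zone is exactly where new families are debated.
#'
#' @param query Amino-acid string.
#' @param references Named list/vector: family id (e.g. `"IC"`) -> reference
#'   amino-acid sequence. Precomputed identities may be supplied instead via
#'   `identities`.
#' @param identities Optional named numeric vector of precomputed identities
#'   (skips alignment).
#' @param member_threshold,novel_threshold Verdict thresholds (70 / 30).
#' @return List of class `FamilyCall`: `closest_family`, `identity`,
#'   `verdict`, `identities`.
#' @export
classify_family <- function(query = NULL, references = NULL,
                            identities = NULL,
                            member_threshold = 70, novel_threshold = 30) {
  if (is.null(identities)) {
    stopifnot(!is.null(references), length(references) > 0,
              !is.null(names(references)))
    identities <- vapply(references, function(r)
      percent_identity(query, r), numeric(1))
  }
  stopifnot(length(identities) > 0, !is.null(names(identities)))
  best <- which.max(identities)
  id <- unname(identities[best])
  verdict <- if (id >= member_threshold) "member"
             else if (max(identities) < novel_threshold) "novel"
             else "borderline"
  structure(list(closest_family = names(identities)[best], identity = id,
                 verdict = verdict, identities = identities),
            class = "FamilyCall")
}

#' @export
print.FamilyCall <- function(x, ...) {
  cat("<FamilyCall> closest ", x$closest_family, " (",
      sprintf("%.1f", x$identity), "% identity): ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Identity-to-distance transform
#'
#' `d = 1 - identity / 100`, the distance scale used for tree building.
#'
#' @param identity Percent identity in `[0, 100]`.
#' @return Numeric distance in `[0, 1]`.
#' @export
identity_to_distance <- function(identity) {
  if (any(identity < 0 | identity > 100)) stop("identity outside [0, 100]")
  1 - identity / 100
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining with the Q-criterion. Ties in the
#' Q-matrix are broken toward the lowest `(i, j)` index pair, so trees are
#' deterministic. Negative branch lengths arising on non-additive matrices
#' are clamped to zero with the deficit shifted to the sister branch (total
#' cherry length preserved). On additive matrices the generating tree is
#' recovered exactly.
#'
#' @param d Symmetric nonnegative distance matrix with zero diagonal,
#'   labeled dimnames, >= 2 taxa (matrix or `dist`).
#' @return Unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(is.na(d)) || any(!is.finite(d))) stop("NaN/NA in distance matrix")
  n <- nrow(d)
  stopifnot(n >= 2L, isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (n == 2L) {
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", labels[1], d[1, 2] / 2,
                   labels[2], d[1, 2] / 2)
    return(ape::read.tree(text = nwk))
  }
  # node representations as partial newick strings
  nodes <- labels
  repeat {
    r <- nrow(d)
    if (r == 3L) break
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, "+")
    diag(q) <- Inf
    # lowest (i, j) with i < j among minima
    qmin <- min(q)
    idx <- which(q - qmin < 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- d[i, j]; li <- 0 }
    if (lj < 0) { li <- d[i, j]; lj <- 0 }
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], li, nodes[j], lj)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], merged)
    rownames(d2) <- colnames(d2) <- seq_len(r - 1L)
    d <- d2
  }
  # resolve the final three nodes around one internal vertex
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[1], l1, nodes[2], l2, nodes[3], l3)
  ape::read.tree(text = nwk)
}

#' Read family reference proteins from FASTA
#'
#' Reference sequences carry their family in the header, e.g.
#' `>EcoR124I_hsdM family=IC`.
#'
#' @param path FASTA path.
#' @return Named list with `seqs` (named character vector) and `families`
#'   (named character vector: sequence name -> family id).
#' @export
read_family_references <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  fam <- regmatches(headers, regexpr("family=\\S+", headers))
  if (length(fam) != length(headers))
    stop("reference FASTA header(s) without family= tag")
  families <- sub("family=", "", fam)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1)
  seqs <- as.character(aa)
  names(seqs) <- ids
  names(families) <- ids
  list(seqs = seqs, families = families)
}
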
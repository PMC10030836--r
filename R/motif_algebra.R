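IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

# complement map over the full degenerate alphabet
.IUPAC_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Degenerate recognition motif
#'
#' Construct a degenerate (IUPAC) recognition motif, optionally annotated with
#' the position and chemistry of the methylated base. This is the unit of all
#' motif algebra in the package: SMRT motif reports, Table-style inventories
#' and genome scanning all speak in these motifs.
#'
#' @param pattern IUPAC nucleotide string (characters `ACGTRYSWKMBDHVN`).
#' @param modified_pos Optional 1-based offset of the methylated base within
#'   `pattern`.
#' @param mod_type Optional modification chemistry, one of `"m6A"`, `"m4C"`,
#'   `"m5C"`.
#' @return An object of class `DegenerateMotif`.
#' @examples
#' degenerate_motif("TCANNNNNNCTC", modified_pos = 3, mod_type = "m6A")
#' @export
degenerate_motif <- function(pattern, modified_pos = NA_integer_,
                             mod_type = NA_character_) {
  pattern <- toupper(as.character(pattern))
  if (length(pattern) != 1L || is.na(pattern) || nchar(pattern) == 0L)
    stop("motif pattern must be a single nonempty string")
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, IUPAC_ALPHABET)
  if (length(bad))
    stop("invalid IUPAC character(s) in motif: ", paste(unique(bad), collapse = ", "))
  if (!is.na(modified_pos)) {
    modified_pos <- as.integer(modified_pos)
    if (modified_pos < 1L || modified_pos > nchar(pattern))
      stop("modified_pos outside pattern")
    if (!is.na(mod_type)) {
      base_set <- iupac_bases(chars[modified_pos])
      need <- switch(mod_type, m6A = "A", m4C = "C", m5C = "C",
                     stop("unknown mod_type: ", mod_type))
      if (!need %in% base_set)
        stop("base at modified_pos (", chars[modified_pos],
             ") is incompatible with ", mod_type)
    }
  }
  structure(list(pattern = pattern, modified_pos = modified_pos,
                 mod_type = mod_type),
            class = "DegenerateMotif")
}

#' @export
print.DegenerateMotif <- function(x, ...) {
  cat("<DegenerateMotif> ", x$pattern, sep = "")
  if (!is.na(x$modified_pos))
    cat("  [", if (is.na(x$mod_type)) "mod" else x$mod_type,
        " at ", x$modified_pos, "]", sep = "")
  cat("\n")
  invisible(x)
}

# accept either a DegenerateMotif or a bare pattern string
.motif_pattern <- function(m) {
  if (inherits(m, "DegenerateMotif")) return(m$pattern)
  degenerate_motif(m)$pattern
}

#' Expand an IUPAC code to its base set
#'
#' @param code single IUPAC character.
#' @return Character vector of the unambiguous bases the code stands for.
#' @export
iupac_bases <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[toupper(code)]], "")[[1]]
}

#' Reverse complement of a degenerate motif
#'
#' Applies the standard IUPAC complement map and reverses the string. The
#' modified-base annotation is deliberately *not* mapped across strands: the
#' methylated base on the opposite strand is an independent biological site
#' (each strand of a motif pair carries its own methylated adenine/cytosine),
#' so strand-specific annotations are always stored per strand.
#'
#' @param m A `DegenerateMotif` or IUPAC pattern string.
#' @return Same type as the input (`DegenerateMotif` in, `DegenerateMotif`
#'   out with the annotation dropped; character in, character out).
#' @examples
#' reverse_complement("TCANNNNNNCTC")  # "GAGNNNNNNTGA"
#' reverse_complement("GCATC")         # "GATGC"
#' @export
reverse_complement <- function(m) {
  pat <- .motif_pattern(m)
  rc <- paste(rev(strsplit(chartr(.IUPAC_FROM, .IUPAC_TO, pat), "")[[1]]),
              collapse = "")
  if (inherits(m, "DegenerateMotif")) degenerate_motif(rc) else rc
}

#' Decompose a bipartite motif into half-sites and spacer
#'
#' Type I recognition motifs are bipartite: two specific 3-4 bp half-sites
#' separated by a nonspecific spacer of Ns (typically 5-8 bp). This finds the
#' single longest internal run of `N` (leftmost on ties, with a warning) of
#' length at least `min_spacer` flanked by non-N sequence on both sides, and
#' returns the decomposition, or `NULL` for non-bipartite motifs.
#'
#' @param m A `DegenerateMotif` or IUPAC pattern string.
#' @param min_spacer Minimum internal N-run length to call a motif bipartite
#'   (default 3; excludes compact type II motifs).
#' @return A list of class `BipartiteDecomposition` with elements `half1`,
#'   `spacer_len`, `half2`, or `NULL`.
#' @examples
#' bipartite_decompose("TCANNNNNNCTC")  # ("TCA", 6, "CTC")
#' bipartite_decompose("GATC")          # NULL
#' @export
bipartite_decompose <- function(m, min_spacer = 3L) {
  pat <- .motif_pattern(m)
  runs <- gregexpr("N+", pat)[[1]]
  if (runs[1] == -1L) return(NULL)
  starts <- as.integer(runs)
  lens <- attr(runs, "match.length")
  internal <- starts > 1L & (starts + lens - 1L) < nchar(pat)
  keep <- internal & lens >= min_spacer
  if (!any(keep)) return(NULL)
  starts <- starts[keep]; lens <- lens[keep]
  best_len <- max(lens)
  idx <- which(lens == best_len)
  if (length(idx) > 1L)
    warning("multiple maximal internal N-runs; decomposing around the leftmost")
  i <- idx[1]
  half1 <- substr(pat, 1L, starts[i] - 1L)
  half2 <- substr(pat, starts[i] + lens[i], nchar(pat))
  if (grepl("N", half1, fixed = TRUE) || grepl("N", half2, fixed = TRUE))
    return(NULL)  # halves must be fully specific
  structure(list(half1 = half1, spacer_len = best_len, half2 = half2),
            class = "BipartiteDecomposition")
}

#' @export
print.BipartiteDecomposition <- function(x, ...) {
  cat("<BipartiteDecomposition> ", x$half1, "-N", x$spacer_len, "-", x$half2,
      "\n", sep = "")
  invisible(x)
}

#' Is a degenerate motif palindromic?
#'
#' True iff the pattern equals its own reverse complement as IUPAC sets
#' (each IUPAC code denotes a unique base set, so string equality after
#' reverse complementation is the set-level test).
#'
#' @inheritParams reverse_complement
#' @return Logical scalar.
#' @examples
#' is_palindromic("GATC")         # TRUE
#' is_palindromic("GCATC")        # FALSE
#' @export
is_palindromic <- function(m) {
  pat <- .motif_pattern(m)
  identical(pat, reverse_complement(pat))
}

#' Scan a genome sequence for a degenerate motif
#'
#' Reports plus-strand hits wherever the pattern's IUPAC sets match, and
#' minus-strand hits wherever the reverse complement of the pattern matches
#' (positions are always the leftmost plus-strand coordinate of the site).
#' Palindromic motifs occur at the same duplex position on both strands and
#' are reported once with strand `"+"`; asymmetric motifs are not
#' deduplicated, so the two members of a motif pair (e.g. GATGC / GCATC)
#' each receive their own strand-specific counts, matching how SMRT motif
#' reports tally `nGenome`. An unknown subject base (`N`) is matched only by
#' a pattern `N`.
#'
#' @param genome_seq Nucleotide string over `A,C,G,T,N`.
#' @param m A `DegenerateMotif` or IUPAC pattern string.
#' @param circular If `TRUE`, matches spanning the origin are included
#'   (the first `min(len(pattern) - 1, len(seq))` bases are wrapped).
#' @return `data.frame` with columns `position` (1-based) and `strand`.
#' @examples
#' scan_motif("GATCGATC", "GATC")   # 2 duplex sites
#' @export
scan_motif <- function(genome_seq, m, circular = FALSE) {
  pat <- .motif_pattern(m)
  genome_seq <- toupper(as.character(genome_seq))
  empty <- data.frame(position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  n <- nchar(genome_seq)
  if (n == 0L) return(empty)
  k <- nchar(pat)
  subject <- genome_seq
  if (circular && k > 1L)
    subject <- paste0(genome_seq, substr(genome_seq, 1L, min(k - 1L, n)))
  if (nchar(subject) < k) return(empty)
  find <- function(p) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(p),
                                     Biostrings::DNAString(subject),
                                     fixed = "subject")
    pos <- BiocGenerics::start(hits)
    sort(unique(ifelse(pos > n, pos - n, pos)))
  }
  plus <- find(pat)
  if (is_palindromic(pat)) {
    if (!length(plus)) return(empty)
    return(data.frame(position = plus, strand = rep("+", length(plus)),
                      stringsAsFactors = FALSE))
  }
  minus <- find(reverse_complement(pat))
  out <- rbind(
    if (length(plus)) data.frame(position = plus, strand = "+",
                                 stringsAsFactors = FALSE),
    if (length(minus)) data.frame(position = minus, strand = "-",
                                  stringsAsFactors = FALSE))
  if (is.null(out)) return(empty)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Modification fraction from site counts
#'
#' The per-motif modification statistic of SMRT motif reports: the share of
#' genomic motif occurrences at which the modification was detected, rounded
#' half-up to the printed precision.
#'
#' @param n_detected Number of detected modified sites.
#' @param n_genome Number of genomic motif occurrences (> 0).
#' @param decimals Decimal places for half-up rounding (default 2, the usual
#'   report precision).
#' @return Numeric proportion in `[0, 1]`.
#' @examples
#' modification_fraction(1118, 1192)        # 0.94
#' modification_fraction(14333, 14382, 3)   # 0.997
#' @export
modification_fraction <- function(n_detected, n_genome, decimals = 2L) {
  if (any(n_genome == 0)) stop("undefined fraction: n_genome is 0")
  if (any(n_detected < 0) || any(n_detected > n_genome))
    stop("n_detected must lie in [0, n_genome]")
  round_half_up(n_detected / n_genome, decimals)
}

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (0.945 -> 0.95), the
#' convention used by printed motif-report fractions; base `round()` uses
#' banker's rounding and is not suitable for reproducing printed tables.
#'
#' @param x Numeric vector.
#' @param decimals Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, decimals = 0L) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Predict the motif recognized by a half-site deletion variant
#'
#' Type I specificity subunits that lose one target recognition domain
#' recognize a symmetrized motif built from the remaining half-site: the
#' kept half `h` with spacer `s` yields `h + N^s + revcomp(h)`, which is
#' palindromic by construction.
#'
#' @param d A `BipartiteDecomposition`.
#' @param kept_half `"first"` or `"second"`: which half-site is retained.
#' @return A `DegenerateMotif` (palindromic at the string level).
#' @examples
#' predict_half_site_motif(bipartite_decompose("TCANNNNNNCTC"), "first")
#' @export
predict_half_site_motif <- function(d, kept_half = c("first", "second")) {
  kept_half <- match.arg(kept_half)
  stopifnot(inherits(d, "BipartiteDecomposition"))
  h <- if (kept_half == "first") d$half1 else reverse_complement(d$half2)
  pat <- paste0(h, strrep("N", d$spacer_len), reverse_complement(h))
  degenerate_motif(pat)
}
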
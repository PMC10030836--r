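# Independent brute-force oracles and small random-input builders used by the
# property-style tests. Oracles are deliberately written as plain
# position-by-position enumeration, independent of the package's code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_aa_str <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_iupac_motif <- function(len, n_degenerate = 1L) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_degenerate > 0L) {
    idx <- sample(len, min(n_degenerate, len))
    chars[idx] <- sample(c("R", "Y", "W", "S", "N"), length(idx),
                         replace = TRUE)
  }
  paste(chars, collapse = "")
}

# does subject base b satisfy IUPAC pattern char p?
# subject N is matched only by pattern N; other degenerate codes require a
# determined base.
oracle_base_match <- function(b, p) {
  if (p == "N") return(TRUE)
  if (b == "N") return(FALSE)
  b %in% iupac_bases(p)
}

oracle_match_positions <- function(seq, pat) {
  n <- nchar(seq); k <- nchar(pat)
  if (n < k || k == 0L) return(integer(0))
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pat, "")[[1]]
  Filter(function(i) all(mapply(oracle_base_match, sc[i:(i + k - 1L)], pc)),
         seq_len(n - k + 1L))
}

oracle_scan <- function(seq, pat, circular = FALSE) {
  n <- nchar(seq); k <- nchar(pat)
  subject <- if (circular && k > 1L && n > 0L)
    paste0(seq, substr(seq, 1L, min(k - 1L, n))) else seq
  wrap <- function(pos) sort(unique(ifelse(pos > n, pos - n, pos)))
  plus <- wrap(unlist(oracle_match_positions(subject, pat)))
  rc <- paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", pat),
                           "")[[1]]), collapse = "")
  if (identical(pat, rc)) {
    return(data.frame(position = as.integer(plus),
                      strand = rep("+", length(plus)),
                      stringsAsFactors = FALSE))
  }
  minus <- wrap(unlist(oracle_match_positions(subject, rc)))
  out <- rbind(
    if (length(plus)) data.frame(position = as.integer(plus), strand = "+",
                                 stringsAsFactors = FALSE),
    if (length(minus)) data.frame(position = as.integer(minus), strand = "-",
                                  stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

oracle_overlap <- function(a_start, a_end, b_start, b_end) {
  length(intersect(seq(a_start, a_end), seq(b_start, b_end)))
}

# brute force: every maximal run of a 4-mer repeated in direct succession
oracle_tandem4 <- function(seq) {
  n <- nchar(seq)
  out <- list()
  covered_until <- 0L
  for (i in seq_len(max(0L, n - 7L))) {
    if (i <= covered_until) next
    unit <- substr(seq, i, i + 3L)
    count <- 1L
    while (substr(seq, i + 4L * count, i + 4L * count + 3L) == unit &&
           i + 4L * count + 3L <= n)
      count <- count + 1L
    if (count >= 2L) {
      out[[length(out) + 1L]] <- list(unit = unit, count = count, start = i)
      covered_until <- i + 4L * count - 1L
    }
  }
  out
}

# brute-force enumeration of gapped short repeats: all k-mer occurrence
# chains with bounded gaps, then maximal-unit suppression; written
# independently of the package's implementation
oracle_short_repeats <- function(seq, kmin = 4L, kmax = 8L, max_gap = 5L) {
  n <- nchar(seq)
  cand <- list()
  for (k in kmax:kmin) {
    if (k > n %/% 2L) next
    pos <- seq_len(n - k + 1L)
    units <- vapply(pos, function(i) substr(seq, i, i + k - 1L), character(1))
    for (u in unique(units[duplicated(units)])) {
      occ <- pos[units == u]
      groups <- list()
      cur <- occ[1]
      for (p in occ[-1]) {
        g <- p - (cur[length(cur)] + k)
        if (g >= 0L && g <= max_gap) cur <- c(cur, p)
        else if (g > max_gap) { groups[[length(groups) + 1L]] <- cur; cur <- p }
      }
      groups[[length(groups) + 1L]] <- cur
      for (gp in groups) if (length(gp) >= 2L)
        cand[[length(cand) + 1L]] <- list(unit = u, positions = gp,
                                          count = length(gp),
                                          gaps = diff(gp) - k)
    }
  }
  if (!length(cand)) return(cand)
  ord <- order(-vapply(cand, function(x) nchar(x$unit), integer(1)))
  keep <- list()
  for (h in cand[ord]) {
    dominated <- any(vapply(keep, function(a) {
      nchar(h$unit) < nchar(a$unit) && grepl(h$unit, a$unit, fixed = TRUE) &&
        h$count == a$count &&
        all(vapply(h$positions, function(p)
          any(p >= a$positions & p + nchar(h$unit) <= a$positions +
                nchar(a$unit)), logical(1)))
    }, logical(1)))
    if (!dominated) keep[[length(keep) + 1L]] <- h
  }
  keep
}

oracle_concordance <- function(mat, vec) {
  apply(mat, 1, function(row) sum(row == vec) / length(vec))
}

make_presence_matrix <- function(mat, sizes = NULL) {
  strains <- paste0("s", seq_len(ncol(mat)))
  fams <- lapply(seq_len(nrow(mat)), function(i)
    paste0("g", i, "_", seq_len(if (is.null(sizes)) 1L else sizes[i])))
  names(fams) <- paste0("fam", seq_len(nrow(mat)))
  dimnames(mat) <- list(names(fams), strains)
  structure(list(matrix = mat, families = fams, strains = strains),
            class = "PresenceMatrix")
}

# a gene table row in the package's layout
gene_row <- function(locus_tag, start, end, strand, product,
                     aa_seq = NA_character_) {
  data.frame(locus_tag = locus_tag, start = start, end = end, strand = strand,
             product = product, nt_len = end - start + 1L, aa_seq = aa_seq,
             stringsAsFactors = FALSE)
}
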
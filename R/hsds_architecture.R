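# HsdS specificity-subunit dissection: per-column conservation of a multiple
# alignment, segmentation into conserved regions (CRs) and target recognition
# domains (TRDs), and amino-acid repeat detection.

#' Per-column conservation profile of a protein alignment
#'
#' The per-column score is the frequency of the modal residue among non-gap
#' characters; columns with more than 50% gaps score 0 (treated as
#' non-conserved). The profile is smoothed with a centered moving average of
#' width `window` (edges use the available part of the window). The
#' modal-frequency score matches the visual "conservation plot" idiom;
#' Shannon-entropy scoring is available via `method = "entropy"`.
#'
#' @param msa Character vector of aligned rows (equal lengths, `-` for gaps),
#'   or a `Biostrings::AAMultipleAlignment`/`AAStringSet`.
#' @param window Smoothing width in columns (odd; default 9).
#' @param method `"modal"` (default) or `"entropy"` (1 - normalized entropy).
#' @return List of class `ConservationProfile`: `columns` (smoothed scores),
#'   `raw`, `n_sequences`, `window`.
#' @export
conservation_profile <- function(msa, window = 9L, method = c("modal", "entropy")) {
  method <- match.arg(method)
  if (inherits(msa, "AAMultipleAlignment")) msa <- as.character(msa)
  if (inherits(msa, "XStringSet")) msa <- as.character(msa)
  msa <- toupper(msa)
  if (length(msa) < 2L) stop("alignment needs >= 2 rows")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("ragged alignment rows")
  mat <- do.call(rbind, strsplit(msa, ""))
  nseq <- nrow(mat)
  raw <- apply(mat, 2, function(col) {
    gaps <- col %in% c("-", ".")
    if (sum(gaps) > nseq / 2) return(0)
    res <- col[!gaps]
    tab <- table(res)
    if (method == "modal") {
      max(tab) / length(res)
    } else {
      p <- tab / length(res)
      h <- -sum(p * log(p))
      hmax <- log(20)
      1 - h / hmax
    }
  })
  smoothed <- .moving_average(raw, window)
  structure(list(columns = smoothed, raw = raw, n_sequences = nseq,
                 window = as.integer(window)),
            class = "ConservationProfile")
}

.moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Segment a conservation profile into CRs and TRDs
#'
#' Maximal runs of columns scoring below `threshold` with length at least
#' `min_len` become TRDs (at most two; if more qualify the two longest are
#' kept with a warning — HsdS subunits carry at most two target recognition
#' domains). The remaining runs are labeled positionally: `N-CR`, `cCR`,
#' `C-CR` around two TRDs; a single `CR` when no TRD is found (the fully
#' conserved, short-subunit case); `TRD1`/flanking CRs for one TRD.
#'
#' @param p A `ConservationProfile` (or bare numeric score vector).
#' @param threshold Score below which a column is variable (default 0.5).
#' @param min_len Minimum TRD length in columns (default 50; TRDs are
#'   ~150 aa domains, 50 avoids noise calls).
#' @return `data.frame` of class `SegmentMap` with columns `label`,
#'   `start_col`, `end_col` (contiguous, covering the alignment).
#' @export
segment_trds <- function(p, threshold = 0.5, min_len = 50L) {
  scores <- if (inherits(p, "ConservationProfile")) p$columns else as.numeric(p)
  n <- length(scores)
  if (!n) stop("empty profile")
  variable <- scores < threshold
  runs <- rle(variable)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  trd_idx <- which(runs$values & runs$lengths >= min_len)
  if (length(trd_idx) == 1L && runs$lengths[trd_idx] == n)
    warning("profile entirely variable; a single TRD spans the alignment")
  if (length(trd_idx) > 2L) {
    warning("more than 2 variable runs qualify as TRDs; keeping the two longest")
    keep <- trd_idx[order(runs$lengths[trd_idx], decreasing = TRUE)][1:2]
    trd_idx <- sort(keep)
  }
  if (!length(trd_idx)) {
    return(structure(data.frame(label = "CR", start_col = 1L, end_col = n,
                                stringsAsFactors = FALSE),
                     class = c("SegmentMap", "data.frame")))
  }
  # segment boundaries: TRD runs split the profile; everything else is CR
  bounds <- sort(unique(c(1L, starts[trd_idx], ends[trd_idx] + 1L, n + 1L)))
  seg_start <- utils::head(bounds, -1L)
  seg_end <- utils::tail(bounds, -1L) - 1L
  is_trd <- seg_start %in% starts[trd_idx]
  n_trd <- sum(is_trd)
  labels <- character(length(seg_start))
  trd_counter <- 0L
  for (k in seq_along(seg_start)) {
    if (is_trd[k]) {
      trd_counter <- trd_counter + 1L
      labels[k] <- paste0("TRD", trd_counter)
    }
  }
  cr_slots <- which(!is_trd)
  if (n_trd == 2L) {
    for (k in cr_slots) {
      labels[k] <- if (seg_end[k] < seg_start[which(is_trd)[1]]) "N-CR"
                   else if (seg_start[k] > seg_end[which(is_trd)[2]]) "C-CR"
                   else "cCR"
    }
  } else {
    for (k in cr_slots) {
      labels[k] <- if (seg_end[k] < seg_start[which(is_trd)[1]]) "N-CR"
                   else "C-CR"
    }
  }
  keep <- seg_end >= seg_start
  structure(data.frame(label = labels[keep], start_col = seg_start[keep],
                       end_col = seg_end[keep], stringsAsFactors = FALSE),
            class = c("SegmentMap", "data.frame"))
}

#' Find tandem tetrapeptide repeats
#'
#' Reports every 4-mer occurring at least twice in direct succession
#' (the hallmark of classical type IC central conserved regions, e.g.
#' TAEL/LEAT/SEAL/TSEL units). Each maximal tandem run is reported once.
#'
#' @param seq Amino-acid string.
#' @return `data.frame` with columns `unit`, `count`, `tandem`, `start`
#'   (1-based position of the first copy); zero rows when none.
#' @export
find_tandem_tetrapeptide_repeats <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  i <- 1L
  while (i + 7L <= n) {
    unit <- substr(seq, i, i + 3L)
    count <- 1L
    while (i + 4L * count + 3L <= n &&
           substr(seq, i + 4L * count, i + 4L * count + 3L) == unit)
      count <- count + 1L
    if (count >= 2L) {
      out[[length(out) + 1L]] <-
        data.frame(unit = unit, count = count, tandem = TRUE, start = i,
                   stringsAsFactors = FALSE)
      i <- i + 4L * count   # skip past the reported run
    } else i <- i + 1L
  }
  if (!length(out))
    return(data.frame(unit = character(0), count = integer(0),
                      tandem = logical(0), start = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Find short (possibly gapped) amino-acid repeats
#'
#' Finds k-mers (`k` in `unit_len_range`) occurring at least twice with
#' inter-copy gaps of at most `max_gap` residues. Maximal units are
#' preferred: a unit is suppressed when it is a substring of a reported
#' longer unit covering the same occurrences (so a 5-mer like LEEQK is
#' reported once, not alongside its constituent 4-mers).
#'
#' @param seq Amino-acid string.
#' @param unit_len_range `(min, max)` unit lengths (default `c(4, 8)`).
#' @param max_gap Maximum residues between consecutive copies (default 5).
#' @return `data.frame` with columns `unit`, `count`, `tandem`, `gaps`
#'   (comma-separated inter-copy gaps), `positions` (comma-separated starts).
#' @export
find_short_repeats <- function(seq, unit_len_range = c(4L, 8L), max_gap = 5L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  hits <- list()
  for (k in seq(unit_len_range[2], unit_len_range[1])) {
    if (k > n %/% 2) next
    starts <- seq_len(n - k + 1L)
    units <- substring(seq, starts, starts + k - 1L)
    for (u in unique(units[duplicated(units)])) {
      pos <- starts[units == u]
      # group positions into chains with gaps <= max_gap, no overlap
      chain <- list(pos[1])
      for (p in pos[-1]) {
        last <- chain[[length(chain)]]
        gap <- p - (last[length(last)] + k)
        if (gap >= 0L && gap <= max_gap)
          chain[[length(chain)]] <- c(last, p)
        else if (gap > max_gap) chain[[length(chain) + 1L]] <- p
        # overlapping later copy: drop it
      }
      for (ch in chain) {
        if (length(ch) < 2L) next
        gaps <- diff(ch) - k
        hits[[length(hits) + 1L]] <-
          list(unit = u, count = length(ch), tandem = all(gaps == 0L),
               gaps = gaps, positions = ch)
      }
    }
  }
  if (!length(hits))
    return(data.frame(unit = character(0), count = integer(0),
                      tandem = logical(0), gaps = character(0),
                      positions = character(0), stringsAsFactors = FALSE))
  # maximal-unit suppression: drop a hit whose unit is a substring of an
  # accepted longer unit with the same copy count and nested positions
  accepted <- list()
  for (h in hits[order(-vapply(hits, function(x) nchar(x$unit), integer(1)))]) {
    suppressed <- FALSE
    for (a in accepted) {
      if (nchar(h$unit) < nchar(a$unit) &&
          grepl(h$unit, a$unit, fixed = TRUE) &&
          h$count == a$count &&
          all(vapply(h$positions, function(p)
            any(p >= a$positions &
                p + nchar(h$unit) - 1L <= a$positions + nchar(a$unit) - 1L),
            logical(1)))) {
        suppressed <- TRUE; break
      }
    }
    if (!suppressed) accepted[[length(accepted) + 1L]] <- h
  }
  do.call(rbind, lapply(accepted, function(h)
    data.frame(unit = h$unit, count = h$count, tandem = h$tandem,
               gaps = paste(h$gaps, collapse = ","),
               positions = paste(h$positions, collapse = ","),
               stringsAsFactors = FALSE)))
}

#' Cross-tabulate central-region repeat counts against motif spacer lengths
#'
#' For a set of specificity subunits with known recognition motifs, tabulates
#' the number of central-region repeats against the bipartite-motif spacer
#' length, and flags records violating a user-supplied expected mapping
#' (repeat count -> admissible spacer lengths). With an empty expected map
#' nothing is flagged.
#'
#' @param records `data.frame` with columns `repeat_count`, `spacer_len`
#'   (and optionally `id`).
#' @param expected Named list: as.character(repeat count) -> integer vector
#'   of admissible spacer lengths.
#' @return List with `table` (contingency table) and `flagged`
#'   (`data.frame` of violating records).
#' @export
correlate_spacer_repeats <- function(records, expected = list()) {
  stopifnot(nrow(records) >= 1L)
  tab <- table(repeat_count = records$repeat_count,
               spacer_len = records$spacer_len)
  flagged <- records[rep(FALSE, nrow(records)), , drop = FALSE]
  if (length(expected)) {
    viol <- vapply(seq_len(nrow(records)), function(i) {
      exp_sp <- expected[[as.character(records$repeat_count[i])]]
      !is.null(exp_sp) && !(records$spacer_len[i] %in% exp_sp)
    }, logical(1))
    flagged <- records[viol, , drop = FALSE]
  }
  list(table = tab, flagged = flagged)
}

#' Read a protein multiple alignment
#'
#' Accepts aligned FASTA or Clustal formats.
#'
#' @param path Alignment file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return Named character vector of aligned rows.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  as.character(aln)  # named by sequence id
}
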
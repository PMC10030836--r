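# External formats: GenBank flat files, SMRT motif summaries, base-modification
# GFF3, Newick trees, and the packaged strain-inventory fixture.
# Coordinates are 1-based inclusive everywhere after parsing.

#' Genome record constructor
#'
#' A single replicon with its annotated CDS set. `genes` is a data.frame with
#' columns `locus_tag, start, end, strand, product, nt_len, aa_seq`
#' (1-based inclusive coordinates, `start <= end`, strand carries orientation).
#'
#' @param replicon_id Nonempty replicon identifier.
#' @param sequence Uppercase nucleotide string (`A,C,G,T,N`).
#' @param genes Gene table (see above); may have zero rows.
#' @param topology `"linear"` or `"circular"`.
#' @param source_kind `"chromosome"`, `"plasmid"` or `"unknown"`.
#' @return Object of class `GenomeRecord`.
#' @export
genome_record <- function(replicon_id, sequence, genes = empty_gene_table(),
                          topology = c("linear", "circular"),
                          source_kind = c("unknown", "chromosome", "plasmid")) {
  topology <- match.arg(topology)
  source_kind <- match.arg(source_kind)
  if (!nzchar(replicon_id)) stop("replicon_id must be nonempty")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over A,C,G,T,N")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    stopifnot(all(c("locus_tag", "start", "end", "strand", "product",
                    "nt_len") %in% names(genes)))
    if (any(genes$start < 1L) || any(genes$end > nchar(sequence)))
      stop("gene coordinates outside [1, sequence length]")
    if (any(genes$start > genes$end)) stop("gene start > end")
    if (!all(genes$strand %in% c("+", "-", ".")))
      stop("gene strand must be +, - or .")
  }
  if (!"aa_seq" %in% names(genes)) genes$aa_seq <- rep(NA_character_, nrow(genes))
  structure(list(replicon_id = replicon_id, topology = topology,
                 sequence = sequence, genes = genes,
                 source_kind = source_kind),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat("<GenomeRecord> ", x$replicon_id, ": ", nchar(x$sequence), " bp, ",
      x$topology, ", ", x$source_kind, ", ", nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
empty_gene_table <- function() {
  data.frame(locus_tag = character(0), start = integer(0), end = integer(0),
             strand = character(0), product = character(0),
             nt_len = integer(0), aa_seq = character(0),
             stringsAsFactors = FALSE)
}

# ---- GenBank flat files ------------------------------------------------------

#' Read a GenBank flat file
#'
#' Parses one `GenomeRecord` per LOCUS. CDS features become gene rows with
#' product text and translation when present; compound (`join(...)`) locations
#' are collapsed to their outer span with a warning (RM genes are single-exon;
#' the precision loss is acceptable and logged). Plasmid/chromosome is taken
#' from the `/plasmid` qualifier of the source feature or from the DEFINITION
#' line; replicons under 500 kb that are circular but unattributed stay
#' `"unknown"` (flagged as likely plasmids in the parse attributes).
#'
#' @param path Path to a GenBank flat file.
#' @return List of `GenomeRecord`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS")))
    stop("malformed GenBank file (no LOCUS line): ", path)
  rec_starts <- which(startsWith(lines, "LOCUS"))
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  lapply(seq_along(rec_starts), function(i)
    .parse_genbank_record(lines[rec_starts[i]:rec_ends[i]], path, rec_starts[i]))
}

.parse_genbank_record <- function(lines, path, offset) {
  locus_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(locus_fields) < 2L)
    stop("malformed LOCUS line at line ", offset, " of ", path)
  replicon_id <- locus_fields[2]
  topology <- if (any(grepl("circular", lines[1]))) "circular" else "linear"
  def <- grep("^DEFINITION", lines, value = TRUE)

  orig <- grep("^ORIGIN", lines)
  sequence <- ""
  if (length(orig)) {
    end <- grep("^//", lines)
    end <- if (length(end)) end[1] - 1L else length(lines)
    seq_lines <- lines[(orig[1] + 1L):end]
    sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  }

  feat_start <- grep("^FEATURES", lines)
  genes <- empty_gene_table()
  source_kind <- "unknown"
  likely_plasmid <- FALSE
  if (length(feat_start)) {
    feat_end <- if (length(orig)) orig[1] - 1L else length(lines)
    flines <- lines[(feat_start[1] + 1L):feat_end]
    # feature blocks begin at column 6 with a key
    is_key <- grepl("^ {1,10}\\S", flines) & !grepl("^ {12,}", flines)
    key_idx <- which(is_key)
    for (j in seq_along(key_idx)) {
      block <- flines[key_idx[j]:(if (j < length(key_idx)) key_idx[j + 1] - 1L
                                  else length(flines))]
      key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
      body <- paste(trimws(block), collapse = "\n")
      if (key == "source") {
        if (grepl("/plasmid", body)) source_kind <- "plasmid"
        else if (grepl("/chromosome", body)) source_kind <- "chromosome"
      } else if (key == "CDS") {
        row <- .parse_cds_block(block, replicon_id)
        if (!is.null(row)) genes <- rbind(genes, row)
      }
    }
  }
  if (source_kind == "unknown") {
    if (any(grepl("plasmid", def, ignore.case = TRUE))) source_kind <- "plasmid"
    else if (any(grepl("chromosome", def, ignore.case = TRUE)))
      source_kind <- "chromosome"
  }
  if (source_kind == "unknown" && topology == "circular" &&
      nchar(sequence) > 0 && nchar(sequence) < 5e5)
    likely_plasmid <- TRUE
  rec <- genome_record(replicon_id, sequence, genes, topology, source_kind)
  attr(rec, "likely_plasmid") <- likely_plasmid
  rec
}

.parse_cds_block <- function(block, replicon_id) {
  loc <- sub("^\\s*CDS\\s+", "", block[1])
  # continuation lines before the first qualifier belong to the location
  i <- 2L
  while (i <= length(block) && !grepl("^\\s*/", block[i])) {
    loc <- paste0(loc, trimws(block[i])); i <- i + 1L
  }
  strand <- if (grepl("complement", loc)) "-" else "+"
  coords <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (!length(coords)) {
    warning("CDS without coordinates skipped on ", replicon_id)
    return(NULL)
  }
  if (grepl("join", loc))
    warning("compound CDS location collapsed to outer span on ", replicon_id)
  start <- min(coords); end <- max(coords)
  quals <- paste(trimws(block[i:length(block)]), collapse = "\n")
  get_qual <- function(name) {
    m <- regmatches(quals, regexpr(paste0('/', name, '="[^"]*"'), quals))
    if (!length(m)) return(NA_character_)
    gsub("\n\\s*", "", sub('"$', "", sub(paste0('/', name, '="'), "", m)))
  }
  translation <- get_qual("translation")
  if (!is.na(translation)) translation <- gsub("\\s", "", translation)
  data.frame(locus_tag = if (is.na(get_qual("locus_tag"))) ""
                         else get_qual("locus_tag"),
             start = start, end = end, strand = strand,
             product = if (is.na(get_qual("product"))) ""
                       else get_qual("product"),
             nt_len = end - start + 1L,
             aa_seq = translation, stringsAsFactors = FALSE)
}

#' Write GenomeRecords as a GenBank flat file
#'
#' Emits LOCUS/DEFINITION/FEATURES/ORIGIN sections sufficient to round-trip
#' through [read_genbank()]: source feature with `/plasmid` qualifier where
#' applicable, CDS features with `/locus_tag`, `/product` and `/translation`.
#'
#' @param records A `GenomeRecord` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "GenomeRecord")) records <- list(records)
  out <- unlist(lapply(records, .format_genbank_record))
  writeLines(out, path)
  invisible(path)
}

.format_genbank_record <- function(rec) {
  n <- nchar(rec$sequence)
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     %s   BCT 01-JAN-2026",
            rec$replicon_id, n,
            if (rec$topology == "circular") "circular" else "linear "),
    sprintf("DEFINITION  synthetic record %s%s.", rec$replicon_id,
            if (rec$source_kind != "unknown") paste0(", ", rec$source_kind)
            else ""),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n))
  if (rec$source_kind == "plasmid")
    lines <- c(lines, sprintf('                     /plasmid="%s"',
                              rec$replicon_id))
  if (rec$source_kind == "chromosome")
    lines <- c(lines, '                     /chromosome="1"')
  g <- rec$genes
  if (nrow(g)) for (i in seq_len(nrow(g))) {
    loc <- sprintf("%d..%d", g$start[i], g$end[i])
    if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     CDS             %s", loc),
               sprintf('                     /locus_tag="%s"', g$locus_tag[i]),
               sprintf('                     /product="%s"', g$product[i]))
    if (!is.na(g$aa_seq[i]) && nzchar(g$aa_seq[i]))
      lines <- c(lines, sprintf('                     /translation="%s"',
                                g$aa_seq[i]))
  }
  lines <- c(lines, "ORIGIN")
  if (n > 0) {
    starts <- seq(1L, n, by = 60L)
    for (s in starts) {
      chunk <- substr(rec$sequence, s, min(s + 59L, n))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", s,
                                tolower(paste(tens, collapse = " "))))
    }
  }
  c(lines, "//")
}

# ---- SMRT motif summary ------------------------------------------------------

.MOTIF_SUMMARY_SYNONYMS <- list(
  motif_string = c("motifstring", "motif"),
  center_pos   = c("centerpos", "center_pos", "modifiedposition"),
  mod_type     = c("mod", "modtype", "modificationtype"),
  fraction     = c("fraction", "frac"),
  n_detected   = c("ndetected", "n_detected"),
  n_genome     = c("ngenome", "n_genome", "nmotifs"),
  mean_score   = c("meanscore", "mean_score", "objectivescore"),
  mean_cov     = c("meancov", "meancoverage", "mean_cov", "meanipdratio_cov")
)

#' Read an SMRT motif-summary table
#'
#' Accepts comma- or tab-delimited tables with at least the standard motif
#' report columns (`MotifString, CenterPos, Mod, Fraction, nDetected, nGenome,
#' MeanScore, MeanCov`); header names are matched case-insensitively with
#' synonyms since report dialects differ between software versions. Unknown
#' extra columns are preserved in the `extra` attribute. Rows whose printed
#' fraction disagrees with `n_detected / n_genome` by more than 0.005
#' (two-decimal rounding slack) trigger a validation warning;
#' `n_detected > n_genome` is an error.
#'
#' @param path Path to the delimited file.
#' @return `data.frame` with one row per motif observation (columns
#'   `motif_string, center_pos, mod_type, fraction, n_detected, n_genome,
#'   mean_score, mean_cov`), class `motif_summary`.
#' @export
read_motif_summary <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first)) stop("empty motif summary file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  lower <- tolower(gsub("[^A-Za-z0-9]", "", names(raw)))
  idx <- vapply(.MOTIF_SUMMARY_SYNONYMS, function(syn) {
    hit <- which(lower %in% gsub("[^a-z0-9]", "", syn))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  missing <- names(idx)[is.na(idx)]
  if (length(missing))
    stop("motif summary is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(
    motif_string = toupper(as.character(raw[[idx["motif_string"]]])),
    center_pos = as.integer(raw[[idx["center_pos"]]]),
    mod_type = as.character(raw[[idx["mod_type"]]]),
    fraction = as.numeric(raw[[idx["fraction"]]]),
    n_detected = as.integer(raw[[idx["n_detected"]]]),
    n_genome = as.integer(raw[[idx["n_genome"]]]),
    mean_score = as.numeric(raw[[idx["mean_score"]]]),
    mean_cov = as.numeric(raw[[idx["mean_cov"]]]),
    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(out$n_detected > out$n_genome))
      stop("invalid motif summary: n_detected > n_genome")
    bad <- !is.na(out$fraction) &
      abs(out$fraction - out$n_detected / out$n_genome) > 0.005
    if (any(bad))
      warning("fraction/count mismatch beyond rounding for motif(s): ",
              paste(out$motif_string[bad], collapse = ", "))
    bad_pos <- out$center_pos < 1L | out$center_pos > nchar(out$motif_string)
    if (any(bad_pos))
      stop("center_pos outside motif for: ",
           paste(out$motif_string[bad_pos], collapse = ", "))
  }
  extra_idx <- setdiff(seq_along(raw), idx)
  attr(out, "extra") <- if (length(extra_idx)) raw[extra_idx] else NULL
  class(out) <- c("motif_summary", "data.frame")
  out
}

#' Write a motif-summary table
#'
#' @param x `data.frame` in the layout produced by [read_motif_summary()].
#' @param path Output path.
#' @param sep Field delimiter (`,` default, or tab).
#' @return `path`, invisibly.
#' @export
write_motif_summary <- function(x, path, sep = ",") {
  out <- data.frame(MotifString = x$motif_string, CenterPos = x$center_pos,
                    Mod = x$mod_type, Fraction = x$fraction,
                    nDetected = x$n_detected, nGenome = x$n_genome,
                    MeanScore = x$mean_score, MeanCov = x$mean_cov)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- base-modification GFF3 --------------------------------------------------

#' Read per-site base-modification calls (SMRT GFF3 dialect)
#'
#' GFF3 with type in `m6A`, `m4C`, `modified_base` and attributes
#' `coverage`, `context`, `IPDRatio`. Strand is mandatory for base
#' modifications: a `.` strand is rejected naming the offending position.
#'
#' @param path Path to the GFF3 file.
#' @return `data.frame` with columns `seqid, position, strand, type, score,
#'   coverage, context, ipd_ratio`.
#' @export
read_basemod_gff <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e)))
  d <- as.data.frame(gr)
  if (!nrow(d))
    return(data.frame(seqid = character(0), position = integer(0),
                      strand = character(0), type = character(0),
                      score = numeric(0), coverage = numeric(0),
                      context = character(0), ipd_ratio = numeric(0),
                      stringsAsFactors = FALSE))
  keep <- as.character(d$type) %in% c("m6A", "m4C", "m5C", "modified_base")
  d <- d[keep, , drop = FALSE]
  strand <- as.character(d$strand)
  if (any(strand == "*"))
    stop("base-modification call without strand at position(s): ",
         paste(d$start[strand == "*"], collapse = ", "))
  data.frame(seqid = as.character(d$seqnames), position = as.integer(d$start),
             strand = strand, type = as.character(d$type),
             score = as.numeric(d$score),
             coverage = if ("coverage" %in% names(d))
               as.numeric(d$coverage) else NA_real_,
             context = if ("context" %in% names(d))
               as.character(d$context) else NA_character_,
             ipd_ratio = if ("IPDRatio" %in% names(d))
               as.numeric(d$IPDRatio) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write per-site base-modification calls as GFF3
#'
#' @param x `data.frame` in the layout produced by [read_basemod_gff()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_basemod_gff <- function(x, path) {
  lines <- "##gff-version 3"
  if (nrow(x)) {
    attrs <- sprintf("coverage=%g;context=%s;IPDRatio=%.2f",
                     x$coverage, x$context, x$ipd_ratio)
    lines <- c(lines, sprintf("%s\tkinModCall\t%s\t%d\t%d\t%g\t%s\t.\t%s",
                              x$seqid, x$type, x$position, x$position,
                              x$score, x$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- packaged strain-inventory fixture --------------------------------------

# md5 of the packaged fixture; any edit to the file breaks the integrity test
.TABLE1_FIXTURE_MD5 <- "f6f46d8d2192ef30c07b88dff9c6afdb"

#' Load the packaged strain RM-inventory fixture
#'
#' The packaged inventory of RM genes across 14 *S. xylosus* strains
#' (locus tag, replicon location, annotation text, gene length with
#' truncation markers, declared RM class, assigned methylation motif).
#' Lengths printed with a `_trunc.` suffix are parsed into a numeric length
#' plus `truncated_flag`. The file is checksummed; an integrity error is
#' raised if it was edited.
#'
#' @param check_integrity Verify the packaged file's md5 (default `TRUE`).
#' @return `data.frame` with columns `strain, locus_tag, location, location_raw,
#'   annotation, nt_len, truncated_flag, declared_class, motif, meth_pos`.
#' @export
load_table1_fixture <- function(check_integrity = TRUE) {
  path <- system.file("extdata", "table1_rm_inventory.tsv",
                      package = "methylRM", mustWork = TRUE)
  if (check_integrity) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .TABLE1_FIXTURE_MD5))
      stop("integrity error: packaged fixture checksum mismatch (", md5, ")")
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE, fill = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  for (col in names(raw)) raw[[col]][is.na(raw[[col]])] <- ""
  trunc <- grepl("trunc", raw$length_nt)
  num <- trimws(sub("_.*$", "", raw$length_nt))
  nt_len <- ifelse(grepl("^[0-9]+$", num), suppressWarnings(as.integer(num)),
                   NA_integer_)
  location <- ifelse(raw$location %in% c("chromosome", "plasmid"),
                     raw$location, "unknown")
  data.frame(strain = raw$strain, locus_tag = raw$locus_tag,
             location = location, location_raw = raw$location,
             annotation = raw$annotation, nt_len = nt_len,
             truncated_flag = trunc,
             declared_class = raw$class, motif = raw$motif,
             meth_pos = raw$meth_pos, stringsAsFactors = FALSE)
}

# ---- Newick ------------------------------------------------------------------

#' Write a phylogenetic tree as Newick text
#'
#' Backed by `ape::write.tree`; duplicate leaf labels are an error and labels
#' containing whitespace are single-quoted per the Newick convention.
#'
#' @param tree An `ape::phylo` object with nonnegative branch lengths.
#' @param path Optional output path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  needs_quote <- grepl("\\s", tree$tip.label)
  orig <- tree$tip.label[needs_quote]
  tree$tip.label[needs_quote] <- paste0("'", orig, "'")
  txt <- ape::write.tree(tree)
  # ape replaces whitespace with underscores even inside quotes; restore
  for (lbl in orig)
    txt <- sub(paste0("'", gsub("\\s", "_", lbl), "'"),
               paste0("'", lbl, "'"), txt, fixed = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#'
#' @param text Newick string (or use `path`).
#' @param path Optional path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) return(ape::read.tree(path))
  ape::read.tree(text = text)
}
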
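# Format boundary: all readers normalize to 0-based half-open coordinates
# and uppercase {A,C,G,T,N}; all writers convert back at the boundary.
# GTF and RepeatMasker .out are 1-based inclusive; BED and the internal
# convention are 0-based half-open.

# Accept a named character vector or a Biostrings XStringSet as a genome.
as_genome <- function(genome) {
  if (methods::is(genome, "XStringSet")) {
    genome <- as.character(genome)
  }
  if (!is.character(genome) || is.null(names(genome)) ||
      any(!nzchar(names(genome)))) {
    validation_error("genome must be a named character vector or DNAStringSet")
  }
  genome
}

# Uppercase, map U->T (with a note), reject anything outside {A,C,G,T,N}.
normalize_sequence <- function(seqs, what = "sequence") {
  seqs <- toupper(seqs)
  n_u <- sum(vapply(gregexpr("U", seqs, fixed = TRUE),
                    function(m) if (m[1] == -1L) 0L else length(m), integer(1)))
  if (n_u > 0) {
    message(sprintf("note: mapped %d U base(s) to T in %s", n_u, what))
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    format_error(sprintf(
      "%s contains characters outside {A,C,G,T,N,U} in record(s): %s",
      what, paste(which(bad), collapse = ", ")
    ))
  }
  seqs
}

#' Read a (multi-record) FASTA file
#'
#' Sequences are uppercased; `U` is mapped to `T` with a logged note; any
#' character outside `{A,C,G,T,N}` after normalization is a format error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of contig sequences (one element per
#'   header, names are the first whitespace-delimited token of the header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) format_error(
                    sprintf("not valid FASTA (%s): %s", path, conditionMessage(e))))
  if (length(set) == 0) format_error(sprintf("empty FASTA file: %s", path))
  nm <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    format_error(sprintf("duplicate contig name(s) in %s: %s",
                         path, paste(dup, collapse = ", ")))
  }
  seqs <- normalize_sequence(as.character(set), what = basename(path))
  if (any(nchar(seqs) == 0)) {
    format_error(sprintf("zero-length record(s) in %s: %s", path,
                         paste(nm[nchar(seqs) == 0], collapse = ", ")))
  }
  names(seqs) <- nm
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

# Parse `key "value"` pairs out of a GTF attribute column.
gtf_attribute <- function(attr, key) {
  m <- regmatches(attr, regexec(sprintf('%s "([^"]*)"', key), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Read transcript models from a GTF file
#'
#' Only `exon` features are used; they must carry Gencode-style `gene_id` and
#' `transcript_id` attributes. 1-based inclusive GTF coordinates are
#' converted to 0-based half-open. Exons are grouped per transcript and
#' sorted by start; overlapping exons within one transcript are a validation
#' error.
#'
#' @param path Path to a GTF file.
#' @return Exon table: data frame with columns `transcript_id`, `gene_id`,
#'   `contig`, `start`, `end`, `strand`, one row per exon, sorted by
#'   (transcript_id, start). The number of non-exon data lines skipped is
#'   recorded in attribute `n_skipped`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  is_data <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- list()
  n_skipped <- 0L
  for (i in which(is_data)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      format_error(sprintf("%s line %d: expected 9 tab-separated fields, got %d",
                           path, i, length(f)))
    }
    if (f[3] != "exon") {
      n_skipped <- n_skipped + 1L
      next
    }
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || start1 > end1) {
      format_error(sprintf("%s line %d: invalid exon coordinates", path, i))
    }
    if (!f[7] %in% c("+", "-")) {
      format_error(sprintf("%s line %d: exon strand must be '+' or '-'", path, i))
    }
    tx <- gtf_attribute(f[9], "transcript_id")
    gn <- gtf_attribute(f[9], "gene_id")
    if (is.na(tx)) {
      format_error(sprintf("%s line %d: exon missing transcript_id attribute",
                           path, i))
    }
    if (is.na(gn)) {
      format_error(sprintf("%s line %d: exon missing gene_id attribute", path, i))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = tx, gene_id = gn, contig = f[1],
      start = start1 - 1L, end = end1, strand = f[7],
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    out <- data.frame(transcript_id = character(0), gene_id = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$transcript_id, out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    validate_transcripts(out)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

# Exon-table invariants: per transcript one contig, one strand, one gene,
# pairwise disjoint exons.
validate_transcripts <- function(transcripts) {
  by_tx <- split(transcripts, transcripts$transcript_id)
  for (tx in names(by_tx)) {
    e <- by_tx[[tx]]
    if (length(unique(e$contig)) != 1L || length(unique(e$strand)) != 1L ||
        length(unique(e$gene_id)) != 1L) {
      validation_error(sprintf(
        "transcript %s: exons must share one contig, strand and gene_id", tx))
    }
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      validation_error(sprintf("transcript %s: overlapping exons", tx))
    }
    if (any(e$start >= e$end)) {
      validation_error(sprintf("transcript %s: empty exon interval", tx))
    }
  }
  invisible(transcripts)
}

#' Write transcript models to GTF
#'
#' Inverse of [read_gtf()]: emits one `exon` feature per exon row with
#' `gene_id`/`transcript_id` attributes, converting back to 1-based
#' inclusive coordinates.
#'
#' @param transcripts Exon table as returned by [read_gtf()].
#' @param path Output path.
#' @param source_label Value for the GTF source column.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(transcripts, path, source_label = "quadedit") {
  tr <- transcripts[order(transcripts$transcript_id, transcripts$start), ,
                    drop = FALSE]
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    tr$contig, source_label, tr$start + 1L, tr$end, tr$strand,
    tr$gene_id, tr$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read repeat annotations
#'
#' Supports RepeatMasker `.out` (1-based inclusive `begin`/`end`, converted
#' on read; a strand of `C` means the repeat matches the minus strand) and
#' BED (passed through as 0-based half-open). The repeat family is taken
#' from the repeat-name column; `family_prefix` optionally restricts to
#' families whose name begins with that prefix (e.g. `"Alu"`).
#'
#' @param path Path to the repeat file.
#' @param dialect `"repeatmasker_out"` or `"bed"`.
#' @param family_prefix Optional prefix filter on the family name.
#' @return Data frame with `contig`, `start`, `end`, `strand`, `family`,
#'   `source_line`.
#' @export
read_repeats <- function(path, dialect = c("repeatmasker_out", "bed"),
                         family_prefix = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || grepl("^#", ln)) next
    if (dialect == "repeatmasker_out") {
      # Skip the two header lines of .out files ("SW ..." / "score ...").
      if (grepl("^\\s*(SW|score)\\b", ln)) next
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 11L) {
        format_error(sprintf(
          "%s line %d: expected >= 11 whitespace-separated columns, got %d",
          path, i, length(f)))
      }
      begin1 <- suppressWarnings(as.integer(f[6]))
      end1 <- suppressWarnings(as.integer(f[7]))
      if (is.na(begin1) || is.na(end1)) {
        format_error(sprintf("%s line %d: non-numeric begin/end", path, i))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig = f[5], start = begin1 - 1L, end = end1,
        strand = if (f[9] == "C") "-" else "+",
        family = f[10], source_line = ln, stringsAsFactors = FALSE
      )
    } else {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 4L) {
        format_error(sprintf(
          "%s line %d: expected >= 4 tab-separated BED columns, got %d",
          path, i, length(f)))
      }
      start0 <- suppressWarnings(as.integer(f[2]))
      end0 <- suppressWarnings(as.integer(f[3]))
      if (is.na(start0) || is.na(end0)) {
        format_error(sprintf("%s line %d: non-numeric start/end", path, i))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig = f[1], start = start0, end = end0,
        strand = if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else ".",
        family = f[4], source_line = ln, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), family = character(0),
               source_line = character(0))
  } else {
    do.call(rbind, rows)
  }
  if (any(!nzchar(out$family))) {
    format_error(sprintf("%s: empty repeat family name", path))
  }
  if (!is.null(family_prefix)) {
    out <- out[startsWith(out$family, family_prefix), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read an editing-site table
#'
#' Tab-separated with a header naming at least `contig`, `position`,
#' `strand` and `gene_id` columns (an `edit_class` column is optional and
#' defaults to `"unknown"`). Positions are normalized to 0-based offsets of
#' the edited adenosine; records keep their input order.
#'
#' @param path Path to the table.
#' @param one_based Set `TRUE` when the file stores 1-based positions.
#' @return Data frame with `contig`, `position`, `strand`, `gene_id`,
#'   `edit_class`.
#' @export
read_edits <- function(path, one_based = FALSE) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("contig", "position", "strand", "gene_id")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    format_error(sprintf("%s: missing required column(s): %s",
                         path, paste(miss, collapse = ", ")))
  }
  if (nrow(tab) == 0) {
    return(data.frame(contig = character(0), position = integer(0),
                      strand = character(0), gene_id = character(0),
                      edit_class = character(0)))
  }
  pos <- suppressWarnings(as.integer(tab$position))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    format_error(sprintf("%s line %d: non-numeric position '%s'",
                         path, bad + 1L, tab$position[bad]))
  }
  bad_strand <- which(!tab$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    format_error(sprintf("%s line %d: strand must be '+' or '-', got '%s'",
                         path, bad_strand[1] + 1L, tab$strand[bad_strand[1]]))
  }
  cls <- if ("edit_class" %in% names(tab)) tab$edit_class else "unknown"
  ok_cls <- c("nonsynonymous", "synonymous", "noncoding", "unknown")
  if (any(!cls %in% ok_cls)) {
    format_error(sprintf("%s: edit_class must be one of %s", path,
                         paste(ok_cls, collapse = ", ")))
  }
  data.frame(
    contig = tab$contig,
    position = pos - as.integer(one_based),
    strand = tab$strand,
    gene_id = tab$gene_id,
    edit_class = cls,
    stringsAsFactors = FALSE
  )
}

#' Write an editing-site table
#'
#' @param edits Edit table as returned by [read_edits()].
#' @param path Output path.
#' @param one_based Write 1-based positions when `TRUE`.
#' @return Invisibly, `path`.
#' @export
write_edits <- function(edits, path, one_based = FALSE) {
  out <- edits[, c("contig", "position", "strand", "gene_id", "edit_class"),
               drop = FALSE]
  out$position <- out$position + as.integer(one_based)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Check edited bases against the genome
#'
#' The base at each edit position on the edit's strand should be adenosine
#' (i.e. `A` on the plus strand, `T` on the plus strand for minus-strand
#' edits). Disagreement is advisory by default: the record is flagged, a
#' single summary warning is raised, and the caller may exclude flagged
#' records. With `strict = TRUE` any disagreement is an error.
#'
#' @param edits Edit table.
#' @param genome Genome as from [read_fasta()].
#' @param strict Escalate disagreements to an error.
#' @return `edits` with an added logical column `ref_ok`.
#' @export
validate_edits <- function(edits, genome, strict = FALSE) {
  genome <- as_genome(genome)
  ok <- logical(nrow(edits))
  for (i in seq_len(nrow(edits))) {
    ctg <- edits$contig[i]
    if (!ctg %in% names(genome)) {
      lookup_error(sprintf("edit %d: contig '%s' not present in genome", i, ctg))
    }
    L <- nchar(genome[[ctg]])
    p <- edits$position[i]
    if (p < 0L || p >= L) {
      ok[i] <- FALSE
      next
    }
    base <- substr(genome[[ctg]], p + 1L, p + 1L)
    expected <- if (edits$strand[i] == "+") "A" else "T"
    ok[i] <- base == expected
  }
  if (any(!ok)) {
    msg <- sprintf("%d edit record(s) whose genome base is not A on the edit strand: rows %s",
                   sum(!ok), paste(utils::head(which(!ok), 10L), collapse = ", "))
    if (strict) validation_error(msg) else warning(msg, call. = FALSE)
  }
  edits$ref_ok <- ok
  edits
}

#' Write intervals as BED6
#'
#' @param records Data frame with `contig`, `start`, `end` and optionally
#'   `name`, `score`, `strand` (missing strand is written as `"."`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(records, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) qe_error(
                    sprintf("cannot open '%s' for writing", path),
                    "quadedit_io_error"))
  on.exit(close(con))
  if (nrow(records) > 0) {
    name <- records$name %||% rep(".", nrow(records))
    score <- records$score %||% rep(0L, nrow(records))
    strand <- records$strand %||% rep(".", nrow(records))
    strand[!strand %in% c("+", "-")] <- "."
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       records$contig, records$start, records$end,
                       name, score, strand), con)
  }
  invisible(path)
}
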
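# Per-edit annotation: windowed same-strand quadruplex association,
# positional classification within transcript isoforms, Alu-repeat overlap
# of the edited exon, and alternative-splicing association via
# isoform-intron overlap.

#' Window configuration for quadruplex association
#'
#' @param flank_bp Half-width of the window around the edited adenosine, in
#'   bp (default 200, i.e. a +/-200 bp window).
#' @param same_strand_only Search only the strand of the edited adenosine
#'   (default `TRUE`).
#' @return An object of class `window_config`.
#' @export
window_config <- function(flank_bp = 200L, same_strand_only = TRUE) {
  flank_bp <- as.integer(flank_bp)
  if (is.na(flank_bp) || flank_bp < 0L) {
    config_error("flank_bp must be an integer >= 0")
  }
  structure(list(flank_bp = flank_bp,
                 same_strand_only = isTRUE(same_strand_only)),
            class = "window_config")
}

positional_classes <- c("first_exon", "last_exon", "internal_exon", "non_exonic")
# Aggregation precedence across isoforms of a gene.
class_precedence <- c("last_exon", "first_exon", "internal_exon", "non_exonic")

# Scan one clamped window around an edit; hits returned in genome coords.
scan_window <- function(genome, contig, position, strand, pattern, window,
                        policy = "canonical") {
  L <- contig_length(genome, contig)
  ws <- max(0L, position - window$flank_bp)
  we <- min(L, position + window$flank_bp + 1L)
  seq <- substr(contig_seq(genome, contig), ws + 1L, we)
  strands <- if (window$same_strand_only) strand else c("+", "-")
  res <- list()
  for (s in strands) {
    if (s == "+") {
      h <- scan_gq(seq, pattern, strand_label = "+", policy = policy)
    } else {
      h <- scan_gq(revcomp(seq), pattern, strand_label = "-", policy = policy)
      if (nrow(h) > 0) h <- mirror_hits(h, nchar(seq))
    }
    if (nrow(h) > 0) {
      h$start <- h$start + ws
      h$end <- h$end + ws
      h$runs <- lapply(h$runs, function(m) m + ws)
      h$loops <- lapply(h$loops, function(m) m + ws)
      res[[length(res) + 1L]] <- h
    }
  }
  if (length(res) == 0) {
    hits <- empty_hits()
  } else {
    hits <- do.call(rbind, res)
    hits <- hits[order(hits$start, hits$end), , drop = FALSE]
    rownames(hits) <- NULL
  }
  list(hits = hits, window_start = ws, window_end = we, window_seq = seq)
}

#' Quadruplex motif search around one edit site
#'
#' Extracts the `[position - flank, position + flank + 1)` window (clamped
#' to contig bounds), scans it on the edit's strand (or both strands when
#' `same_strand_only = FALSE`), and reports the signed distance
#' `hit start - edit position` in plus-strand coordinates, minimized by
#' absolute value (ties resolved toward the upstream, i.e. more negative,
#' value).
#'
#' @param edit One-row data frame or list with `contig`, `position`,
#'   `strand`.
#' @param genome Genome as from [read_fasta()].
#' @param pattern A [gq_pattern()].
#' @param window A [window_config()].
#' @return List with `found` (logical), `min_distance_bp` (NA when not
#'   found), and `hits` (data frame in genome coordinates, with `contig`).
#' @export
gq_near_edit <- function(edit, genome, pattern = gq_pattern(),
                         window = window_config()) {
  genome <- as_genome(genome)
  sw <- scan_window(genome, edit$contig, as.integer(edit$position),
                    edit$strand, pattern, window)
  hits <- sw$hits
  if (nrow(hits) == 0) {
    return(list(found = FALSE, min_distance_bp = NA_integer_,
                hits = empty_hits(contig_col = TRUE)))
  }
  d <- hits$start - as.integer(edit$position)
  ord <- order(abs(d), d)
  hits <- cbind(data.frame(contig = edit$contig, stringsAsFactors = FALSE),
                hits)
  list(found = TRUE, min_distance_bp = d[ord[1]], hits = hits)
}

# Sorted exon starts/ends of one transcript.
transcript_introns <- function(exons) {
  e <- exons[order(exons$start), , drop = FALSE]
  if (nrow(e) < 2L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = e$end[-nrow(e)], end = e$start[-1L])
}

#' Positional classification of an edit within transcript isoforms
#'
#' Per transcript of the edit's gene: `first_exon` when the edit lies in the
#' 5'-most exon in transcript orientation (the genomically last exon for a
#' minus-strand transcript), `last_exon` for the 3'-most, `internal_exon`
#' otherwise when exonic, `non_exonic` when in no exon. Single-exon
#' transcripts classify as `last_exon`. The aggregate class across isoforms
#' uses the precedence `last_exon > first_exon > internal_exon >
#' non_exonic`.
#'
#' @param edit One-row data frame or list with `contig`, `position`,
#'   `gene_id`.
#' @param transcripts Exon table (see [read_gtf()]).
#' @return List with `per_transcript` (data frame `transcript_id`, `class`)
#'   and `aggregate` (single class string).
#' @export
classify_edit <- function(edit, transcripts) {
  tr <- transcripts[transcripts$gene_id == edit$gene_id &
                      transcripts$contig == edit$contig, , drop = FALSE]
  p <- as.integer(edit$position)
  tx_ids <- sort(unique(tr$transcript_id))
  cls <- vapply(tx_ids, function(tx) {
    e <- tr[tr$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    hit <- which(e$start <= p & p < e$end)
    if (length(hit) == 0) return("non_exonic")
    k <- nrow(e)
    if (k == 1L) return("last_exon")
    idx <- hit[1]
    first_idx <- if (e$strand[1] == "+") 1L else k
    last_idx <- if (e$strand[1] == "+") k else 1L
    if (idx == last_idx) "last_exon"
    else if (idx == first_idx) "first_exon"
    else "internal_exon"
  }, character(1))
  aggregate <- "non_exonic"
  for (c0 in class_precedence) {
    if (c0 %in% cls) {
      aggregate <- c0
      break
    }
  }
  list(
    per_transcript = data.frame(transcript_id = tx_ids, class = unname(cls),
                                stringsAsFactors = FALSE),
    aggregate = aggregate
  )
}

# Lower-midpoint median: for an even count, the smaller of the two central
# order statistics (documented convention for integer overlap lengths).
overlap_median <- function(x, method = c("lower", "midpoint")) {
  method <- match.arg(method)
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (method == "midpoint") return(stats::median(x))
  sort(x)[ceiling(n / 2)]
}

#' Overlaps between edited exons and repeat annotations
#'
#' One record per intersecting (exon, repeat) pair, computed with
#' [IRanges::findOverlaps()]. The summary is over the per-exon maximal
#' overlap; its median uses the lower-midpoint convention for even counts.
#'
#' @param edited_exons Data frame with `contig`, `start`, `end` and
#'   optionally `gene_id`.
#' @param repeats Repeat table (see [read_repeats()]), already filtered to
#'   the families of interest.
#' @return List with `records` (data frame `exon_idx`, `repeat_idx`,
#'   `contig`, `exon_start`, `exon_end`, `family`, `overlap_bp`) and
#'   `summary` (list `min`, `max`, `median`, `mean`, `n_exons`, `n_genes`;
#'   all-NA with `n_exons = 0` when there is no overlap).
#' @export
exon_repeat_overlaps <- function(edited_exons, repeats) {
  records <- data.frame(
    exon_idx = integer(0), repeat_idx = integer(0), contig = character(0),
    exon_start = integer(0), exon_end = integer(0), family = character(0),
    overlap_bp = integer(0)
  )
  if (nrow(edited_exons) > 0 && nrow(repeats) > 0) {
    rows <- list()
    for (ctg in unique(edited_exons$contig)) {
      ei <- which(edited_exons$contig == ctg)
      ri <- which(repeats$contig == ctg)
      if (length(ri) == 0) next
      # IRanges is 1-based closed; [start, end) maps to start+1 .. end.
      eq <- IRanges::IRanges(start = edited_exons$start[ei] + 1L,
                             end = edited_exons$end[ei])
      rq <- IRanges::IRanges(start = repeats$start[ri] + 1L,
                             end = repeats$end[ri])
      ov <- IRanges::findOverlaps(eq, rq, minoverlap = 1L)
      if (length(ov) == 0) next
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(eq[qh], rq[sh]))
      rows[[length(rows) + 1L]] <- data.frame(
        exon_idx = ei[qh], repeat_idx = ri[sh], contig = ctg,
        exon_start = edited_exons$start[ei[qh]],
        exon_end = edited_exons$end[ei[qh]],
        family = repeats$family[ri[sh]],
        overlap_bp = as.integer(w), stringsAsFactors = FALSE
      )
    }
    if (length(rows) > 0) {
      records <- do.call(rbind, rows)
      records <- records[order(records$exon_idx, records$repeat_idx), ,
                         drop = FALSE]
      rownames(records) <- NULL
    }
  }
  if (nrow(records) == 0) {
    summary <- list(min = NA_real_, max = NA_real_, median = NA_real_,
                    mean = NA_real_, n_exons = 0L, n_genes = 0L)
  } else {
    per_exon <- tapply(records$overlap_bp, records$exon_idx, max)
    n_genes <- if ("gene_id" %in% names(edited_exons)) {
      length(unique(edited_exons$gene_id[as.integer(names(per_exon))]))
    } else {
      NA_integer_
    }
    summary <- list(
      min = min(per_exon), max = max(per_exon),
      median = overlap_median(as.numeric(per_exon)),
      mean = mean(per_exon),
      n_exons = length(per_exon), n_genes = n_genes
    )
  }
  list(records = records, summary = summary)
}

#' Alternative-splicing association of an edited exon
#'
#' `TRUE` when some other isoform of the same gene has an intron (the gap
#' between consecutive exons) overlapping the edited exon by at least 1 bp
#' -- the isoform-intron overlap criterion for associating editing with
#' alternative splicing.
#'
#' @param gene_transcripts Exon table restricted to one gene.
#' @param edited_exon List or one-row data frame with `contig`, `start`,
#'   `end` matching an exon of at least one supplied transcript exactly.
#' @return Logical scalar.
#' @export
splice_association <- function(gene_transcripts, edited_exon) {
  tr <- gene_transcripts[gene_transcripts$contig == edited_exon$contig, ,
                         drop = FALSE]
  if (nrow(tr) == 0) {
    validation_error("no transcripts supplied on the edited exon's contig")
  }
  has_exon <- vapply(split(tr, tr$transcript_id), function(e) {
    any(e$start == edited_exon$start & e$end == edited_exon$end)
  }, logical(1))
  if (!any(has_exon)) {
    validation_error(sprintf(
      "interval [%d,%d) is not an exon of any supplied transcript",
      edited_exon$start, edited_exon$end))
  }
  for (tx in names(has_exon)[!has_exon]) {
    introns <- transcript_introns(tr[tr$transcript_id == tx, , drop = FALSE])
    if (any(introns$start < edited_exon$end &
              edited_exon$start < introns$end)) {
      return(TRUE)
    }
  }
  FALSE
}

# Unique exon intervals of a gene's transcripts containing position p.
containing_exons <- function(transcripts, edit) {
  tr <- transcripts[transcripts$gene_id == edit$gene_id &
                      transcripts$contig == edit$contig, , drop = FALSE]
  p <- as.integer(edit$position)
  hit <- tr[tr$start <= p & p < tr$end, , drop = FALSE]
  if (nrow(hit) == 0) return(hit)
  hit <- hit[!duplicated(hit[, c("start", "end")]), , drop = FALSE]
  hit[order(hit$start, hit$end), , drop = FALSE]
}

#' Annotate all edit sites
#'
#' Composes [gq_near_edit()], [classify_edit()], [exon_repeat_overlaps()],
#' [splice_association()] and [edit_enabled_gq()] per edit. Splice
#' association is computed only for exonic edits whose window contains a
#' quadruplex motif (the conditioning used when edited exons associated with
#' quadruplex motifs are intersected with the introns of other isoforms);
#' other edits report `FALSE`. Records whose genome base is not A on the
#' edit strand are flagged `excluded` and carry NA annotation fields (an
#' error in strict mode).
#'
#' @param edits Edit table (see [read_edits()]).
#' @param genome Genome (see [read_fasta()]).
#' @param transcripts Exon table (see [read_gtf()]).
#' @param repeats Repeat table (see [read_repeats()]); filtered here to
#'   `alu_prefix` families.
#' @param pattern A [gq_pattern()].
#' @param window A [window_config()].
#' @param alu_prefix Repeat-family prefix retained for overlap computation
#'   (default `"Alu"`).
#' @param strict Escalate per-record validation problems to errors.
#' @return Annotation table: one row per input edit, in input order, with
#'   columns `contig`, `position`, `strand`, `gene_id`, `edit_class`,
#'   `excluded`, `aggregate_class`, `per_transcript_classes` (collapsed
#'   `tx:class` string), `gq_found`, `gq_min_distance_bp`, `alu_overlap_bp`,
#'   `splice_associated`, `edit_enabled`.
#' @export
annotate_all <- function(edits, genome, transcripts, repeats,
                         pattern = gq_pattern(), window = window_config(),
                         alu_prefix = "Alu", strict = FALSE) {
  genome <- as_genome(genome)
  if (nrow(edits) == 0) {
    return(data.frame(
      contig = character(0), position = integer(0), strand = character(0),
      gene_id = character(0), edit_class = character(0),
      excluded = logical(0), aggregate_class = character(0),
      per_transcript_classes = character(0),
      exon_start = integer(0), exon_end = integer(0), gq_found = logical(0),
      gq_min_distance_bp = integer(0), alu_overlap_bp = integer(0),
      splice_associated = logical(0), edit_enabled = logical(0)
    ))
  }
  edits <- validate_edits(edits, genome, strict = strict)
  alu <- repeats[startsWith(repeats$family, alu_prefix), , drop = FALSE]
  n <- nrow(edits)
  out <- data.frame(
    contig = edits$contig, position = edits$position, strand = edits$strand,
    gene_id = edits$gene_id, edit_class = edits$edit_class,
    excluded = !edits$ref_ok,
    aggregate_class = NA_character_, per_transcript_classes = NA_character_,
    exon_start = NA_integer_, exon_end = NA_integer_,
    gq_found = NA, gq_min_distance_bp = NA_integer_,
    alu_overlap_bp = NA_integer_, splice_associated = NA,
    edit_enabled = NA, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    if (out$excluded[i]) next
    edit <- edits[i, , drop = FALSE]
    gq <- gq_near_edit(edit, genome, pattern, window)
    cls <- classify_edit(edit, transcripts)
    out$gq_found[i] <- gq$found
    out$gq_min_distance_bp[i] <- gq$min_distance_bp
    out$aggregate_class[i] <- cls$aggregate
    out$per_transcript_classes[i] <- paste(
      sprintf("%s:%s", cls$per_transcript$transcript_id,
              cls$per_transcript$class), collapse = ",")
    exons <- containing_exons(transcripts, edit)
    if (nrow(exons) == 0) {
      out$alu_overlap_bp[i] <- 0L
      out$splice_associated[i] <- FALSE
    } else {
      out$exon_start[i] <- exons$start[1]
      out$exon_end[i] <- exons$end[1]
      ov <- exon_repeat_overlaps(exons, alu)
      out$alu_overlap_bp[i] <-
        if (ov$summary$n_exons == 0) 0L else as.integer(ov$summary$max)
      if (gq$found) {
        gene_tr <- transcripts[transcripts$gene_id == edit$gene_id, ,
                               drop = FALSE]
        out$splice_associated[i] <- any(vapply(seq_len(nrow(exons)),
          function(j) splice_association(gene_tr, exons[j, , drop = FALSE]),
          logical(1)))
      } else {
        out$splice_associated[i] <- FALSE
      }
    }
    out$edit_enabled[i] <- edit_completes_gq(edit, genome, pattern, window)
  }
  out
}

# Does substituting this edited A by G create a quadruplex hit covering the
# edit within its window? Evaluated on the edit's strand.
edit_completes_gq <- function(edit, genome, pattern, window) {
  L <- contig_length(genome, edit$contig)
  p <- as.integer(edit$position)
  ws <- max(0L, p - window$flank_bp)
  we <- min(L, p + window$flank_bp + 1L)
  seq <- substr(contig_seq(genome, edit$contig), ws + 1L, we)
  if (edit$strand == "+") {
    off <- p - ws
  } else {
    seq <- revcomp(seq)
    off <- (we - ws) - 1L - (p - ws)
  }
  res <- edit_enabled_gq(seq, off, pattern)[[1]]
  isTRUE(res$ok) && nrow(res$new_hits) > 0
}

#' Write an annotation table
#'
#' Tab-separated, one row per edit, columns as in [annotate_all()].
#'
#' @param annotations Annotation table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
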
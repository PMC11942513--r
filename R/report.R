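# Summary statistics over an annotation table, and a permutation-based
# enrichment test of quadruplex-edit association. The enrichment test is an
# extension beyond the descriptive association counts: it repositions each
# edit uniformly within its host transcript's exonic space (strand
# preserved) to form the null.

#' Summarize an annotation table
#'
#' Computes the counts and fractions the pipeline reports: positional-class
#' fractions (with all three denominators: edits, distinct edited exons,
#' genes), quadruplex association count, the Alu-overlap summary over
#' per-exon maximal overlaps, and the count/fraction of genes with
#' splice-associated editing. Excluded records (failed reference-base check)
#' are dropped from all denominators.
#'
#' @param annotations Annotation table from [annotate_all()].
#' @return An object of class `summary_report`: a list with `n_edits`,
#'   `n_excluded`, `n_genes`, `n_exons`, `class_fractions` (a matrix,
#'   denominators in rows), `n_gq_associated`, `alu_overlap_summary`,
#'   `n_splice_associated_genes`, `frac_splice_associated_genes`.
#' @export
summarize_annotations <- function(annotations) {
  ann <- annotations[!annotations$excluded, , drop = FALSE]
  n_edits <- nrow(ann)
  genes <- unique(ann$gene_id)
  exon_key <- ifelse(is.na(ann$exon_start), NA_character_,
                     paste(ann$contig, ann$exon_start, ann$exon_end, sep = ":"))
  n_exons <- length(unique(stats::na.omit(exon_key)))

  frac_over <- function(cls) {
    if (length(cls) == 0) {
      return(stats::setNames(rep(NA_real_, length(positional_classes)),
                             positional_classes))
    }
    tab <- table(factor(cls, levels = positional_classes))
    stats::setNames(as.numeric(tab) / length(cls), positional_classes)
  }
  # Denominator "exons": one vote per distinct edited exon (exonic edits
  # only); "genes": one vote per gene using the aggregation precedence.
  exonic <- !is.na(exon_key)
  exon_cls <- tapply(ann$aggregate_class[exonic], exon_key[exonic],
                     function(v) {
                       for (c0 in class_precedence) if (c0 %in% v) return(c0)
                       v[1]
                     })
  gene_cls <- tapply(ann$aggregate_class, ann$gene_id, function(v) {
    for (c0 in class_precedence) if (c0 %in% v) return(c0)
    v[1]
  })
  class_fractions <- rbind(
    edits = frac_over(ann$aggregate_class),
    exons = frac_over(as.character(exon_cls)),
    genes = frac_over(as.character(gene_cls))
  )

  # Alu-overlap summary over distinct edited exons with positive overlap.
  ov <- ann$alu_overlap_bp
  has_ov <- !is.na(ov) & ov > 0 & exonic
  per_exon <- if (any(has_ov)) {
    tapply(ov[has_ov], exon_key[has_ov], max)
  } else {
    numeric(0)
  }
  alu_summary <- if (length(per_exon) == 0) {
    list(min = NA_real_, max = NA_real_, median = NA_real_, mean = NA_real_,
         n_exons = 0L,
         n_genes = 0L)
  } else {
    list(min = min(per_exon), max = max(per_exon),
         median = overlap_median(as.numeric(per_exon)), mean = mean(per_exon),
         n_exons = length(per_exon),
         n_genes = length(unique(ann$gene_id[has_ov])))
  }

  splice_genes <- unique(ann$gene_id[ann$splice_associated %in% TRUE])
  structure(list(
    n_edits = n_edits,
    n_excluded = sum(annotations$excluded),
    n_genes = length(genes),
    n_exons = n_exons,
    class_fractions = class_fractions,
    n_gq_associated = sum(ann$gq_found %in% TRUE),
    alu_overlap_summary = alu_summary,
    n_splice_associated_genes = length(splice_genes),
    frac_splice_associated_genes =
      if (length(genes) == 0) NA_real_ else length(splice_genes) / length(genes)
  ), class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("<summary_report> %d edits (%d excluded), %d genes, %d edited exons\n",
              x$n_edits, x$n_excluded, x$n_genes, x$n_exons))
  cat("class fractions (over edits):\n")
  print(round(x$class_fractions["edits", ], 4))
  cat(sprintf("GQ-associated edits: %d\n", x$n_gq_associated))
  s <- x$alu_overlap_summary
  cat(sprintf("Alu overlap: n_exons=%d, range=%s-%s, median=%s, mean=%s\n",
              s$n_exons, s$min, s$max, s$median,
              if (is.na(s$mean)) NA else round(s$mean, 2)))
  cat(sprintf("splice-associated genes: %d (%s)\n",
              x$n_splice_associated_genes,
              if (is.na(x$frac_splice_associated_genes)) "NA" else
                sprintf("%.1f%%", 100 * x$frac_splice_associated_genes)))
  invisible(x)
}

#' Write a summary report as a tab-separated key/value table
#'
#' @param report A `summary_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(report, path) {
  rows <- c(
    sprintf("n_edits\t%d", report$n_edits),
    sprintf("n_excluded\t%d", report$n_excluded),
    sprintf("n_genes\t%d", report$n_genes),
    sprintf("n_exons\t%d", report$n_exons),
    vapply(rownames(report$class_fractions), function(dn) {
      paste(sprintf("class_frac_%s_%s\t%s", dn,
                    colnames(report$class_fractions),
                    report$class_fractions[dn, ]), collapse = "\n")
    }, character(1)),
    sprintf("n_gq_associated\t%d", report$n_gq_associated),
    sprintf("alu_overlap_%s\t%s", names(report$alu_overlap_summary),
            unlist(report$alu_overlap_summary)),
    sprintf("n_splice_associated_genes\t%d", report$n_splice_associated_genes),
    sprintf("frac_splice_associated_genes\t%s",
            report$frac_splice_associated_genes)
  )
  writeLines(unlist(rows), path)
  invisible(path)
}

# Fast window-association check used by the permutation test: a quadruplex
# hit is associated with position p iff the hit lies entirely within the
# clamped window [p - flank, p + flank + 1). Scanning the extracted window
# is equivalent: a hit of the whole contig is found in the window iff it is
# contained in it (truncating a maximal G-run at the window edge leaves a
# run suffix, which the canonical policy also admits as a match start).
window_associated <- function(hit_start, hit_end, p, flank, L) {
  ws <- pmax(0L, p - flank)
  we <- pmin(L, p + flank + 1L)
  any(hit_start >= ws & hit_end <= we)
}

#' Permutation test for quadruplex-edit association
#'
#' The observed statistic is the number of (non-excluded, exonic) edits with
#' a quadruplex motif in their window. Each permutation repositions every
#' edit uniformly within its host transcript's exonic space (strand and
#' host transcript preserved) and recounts. The p-value uses the add-one
#' convention `p = (1 + #(null >= observed)) / (1 + n_permutations)`, so
#' `1/(N+1) <= p <= 1`.
#'
#' Edits lying in no exon of any transcript of their gene have no host
#' transcript; they are excluded with a logged count.
#'
#' @param edits Edit table.
#' @param genome Genome.
#' @param transcripts Exon table.
#' @param pattern A [gq_pattern()].
#' @param window A [window_config()].
#' @param n_permutations Number of permutations (>= 1, default 999).
#' @param seed Integer seed (required, for reproducibility).
#' @return List of class `enrichment_result`: `observed`, `null_counts`,
#'   `p_value`, `n_permutations`, `seed`, `n_edits_used`, `n_excluded`.
#' @export
gq_enrichment <- function(edits, genome, transcripts,
                          pattern = gq_pattern(), window = window_config(),
                          n_permutations = 999L, seed) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    config_error("n_permutations must be >= 1")
  }
  if (missing(seed) || is.na(as.integer(seed))) {
    config_error("an integer seed is required")
  }
  genome <- as_genome(genome)

  # Host transcript: first (sorted) transcript of the edit's gene having the
  # edit in one of its exons.
  host <- character(nrow(edits))
  for (i in seq_len(nrow(edits))) {
    tr <- transcripts[transcripts$gene_id == edits$gene_id[i] &
                        transcripts$contig == edits$contig[i], , drop = FALSE]
    p <- edits$position[i]
    in_exon <- tr[tr$start <= p & p < tr$end, , drop = FALSE]
    host[i] <- if (nrow(in_exon) == 0) NA_character_ else
      sort(unique(in_exon$transcript_id))[1]
  }
  n_excluded <- sum(is.na(host))
  if (n_excluded > 0) {
    message(sprintf("gq_enrichment: excluded %d edit(s) without a host transcript",
                    n_excluded))
  }
  keep <- which(!is.na(host))
  if (length(keep) == 0) config_error("no edits with a host transcript")

  # One genome scan per (contig, strand) actually needed.
  need <- unique(data.frame(contig = edits$contig[keep],
                            strand = edits$strand[keep]))
  hit_cache <- list()
  for (j in seq_len(nrow(need))) {
    ctg <- need$contig[j]
    str <- need$strand[j]
    seq <- contig_seq(genome, ctg)
    h <- if (!window$same_strand_only || str == "+") {
      scan_gq(seq, pattern, strand_label = "+")
    } else {
      empty_hits()
    }
    h2 <- if (!window$same_strand_only || str == "-") {
      hh <- scan_gq(revcomp(seq), pattern, strand_label = "-")
      if (nrow(hh) > 0) mirror_hits(hh, nchar(seq)) else hh
    } else {
      empty_hits()
    }
    hh <- rbind(h, h2)
    hit_cache[[paste0(ctg, "/", str)]] <- hh[, c("start", "end")]
  }
  assoc_count <- function(pos_vec) {
    n <- 0L
    for (k in seq_along(keep)) {
      i <- keep[k]
      key <- paste0(edits$contig[i], "/", edits$strand[i])
      hh <- hit_cache[[key]]
      if (nrow(hh) == 0) next
      L <- nchar(genome[[edits$contig[i]]])
      if (window_associated(hh$start, hh$end, pos_vec[k], window$flank_bp, L)) {
        n <- n + 1L
      }
    }
    n
  }

  observed <- assoc_count(edits$position[keep])

  # Exonic coordinate maps of each host transcript.
  exon_maps <- lapply(keep, function(i) {
    e <- transcripts[transcripts$transcript_id == host[i], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    list(starts = e$start, widths = e$end - e$start,
         total = sum(e$end - e$start))
  })

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  null_counts <- integer(n_permutations)
  for (b in seq_len(n_permutations)) {
    pos <- vapply(exon_maps, function(m) {
      u <- sample.int(m$total, 1L) - 1L # 0-based offset into exonic space
      cum <- cumsum(m$widths)
      j <- which(u < cum)[1]
      m$starts[j] + u - (if (j == 1L) 0L else cum[j - 1L])
    }, integer(1))
    null_counts[b] <- assoc_count(pos)
  }
  p_value <- (1 + sum(null_counts >= observed)) / (1 + n_permutations)
  structure(list(
    observed = observed, null_counts = null_counts, p_value = p_value,
    n_permutations = n_permutations, seed = as.integer(seed),
    n_edits_used = length(keep), n_excluded = n_excluded
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> observed=%d over %d edits; null mean=%.2f; p=%.4g (N=%d, seed=%d)\n",
    x$observed, x$n_edits_used, mean(x$null_counts), x$p_value,
    x$n_permutations, x$seed))
  invisible(x)
}
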
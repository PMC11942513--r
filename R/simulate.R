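# Synthetic genomes with planted, recorded truth.
#
# Design for exact truth recovery:
#  * one gene per contig, one edit per gene, so every +/-flank window
#    contains only the elements planted for its own edit;
#  * background sequence carries no GG and no CC dinucleotide, and motif
#    loops are drawn from {A,T}; hence, on either strand, the only G-runs of
#    length >= 2 anywhere in the genome are planted motif runs on their
#    intended strand -- background can never match the quadruplex grammar;
#  * planted motif runs are exactly two G long, so the canonical scanner
#    reports exactly one hit per planted motif (no alternative match start);
#  * all planted elements keep >= 12 bp of background between them (more
#    than the maximal loop), so runs of different elements cannot chain
#    into a spurious match;
#  * bases flanking each planted element and each edit are forced non-G, so
#    an A-to-G substitution at a non-edit-enabled edit can never seed or
#    extend a run.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the study conditions the pipeline targets: the positional
#' class mixture 0.17/0.59/0.19/0.05 (first/last/internal/non-exonic) and
#' Alu overlap lengths of 5-322 bp.
#'
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @param n_genes Number of genes (one gene per contig, one edit per gene).
#' @param isoforms_per_gene Range (lo, hi) of isoforms per gene.
#' @param exons_per_transcript Range of exons in the primary isoform (>= 3).
#' @param exon_len,intron_len Ranges in bp.
#' @param gc_fraction Target GC of the background draw (before GG/CC
#'   suppression, which lowers it slightly).
#' @param class_mixture Named fractions over the four positional classes;
#'   must sum to 1.
#' @param gq_prob Per-edit probability of planting a quadruplex motif in
#'   the window.
#' @param gq_distance Range of |planted motif start - edit position| in bp.
#' @param alu_prob Per-edited-exon probability of planting an Alu-like
#'   repeat interval partially overlapping the exon.
#' @param alu_overlap Range of planted overlap lengths in bp (clamped to
#'   the exon length).
#' @param splice_prob Probability that a quadruplex-associated exonic edit
#'   gets a skip isoform whose intron spans the edited exon.
#' @param edit_enabled_fraction Fraction of edits planted so that the A-to-G
#'   substitution completes a quadruplex.
#' @param decoy_repeat_prob Probability of an additional non-Alu decoy
#'   repeat on the edited exon (exercises the family filter; not truth).
#' @param background_gq_per_gene Poisson mean of extra motifs planted
#'   uniformly per gene, independent of the edit. Intended for permutation
#'   null calibration only: when > 0 the per-edit `gq_planted`/`gq_distance`
#'   truth columns no longer predict the scan result.
#' @param flank_bp Window half-width the dataset is built for.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 2000L,
                             isoforms_per_gene = c(1L, 3L),
                             exons_per_transcript = c(3L, 6L),
                             exon_len = c(120L, 400L),
                             intron_len = c(200L, 600L),
                             gc_fraction = 0.45,
                             class_mixture = c(first_exon = 0.17,
                                               last_exon = 0.59,
                                               internal_exon = 0.19,
                                               non_exonic = 0.05),
                             gq_prob = 0.5,
                             gq_distance = c(20L, 150L),
                             alu_prob = 0.5,
                             alu_overlap = c(5L, 322L),
                             splice_prob = 0.5,
                             edit_enabled_fraction = 0.1,
                             decoy_repeat_prob = 0.1,
                             background_gq_per_gene = 0,
                             flank_bp = 200L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              exons_per_transcript = as.integer(exons_per_transcript),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              gc_fraction = gc_fraction,
              class_mixture = class_mixture,
              gq_prob = gq_prob, gq_distance = as.integer(gq_distance),
              alu_prob = alu_prob, alu_overlap = as.integer(alu_overlap),
              splice_prob = splice_prob,
              edit_enabled_fraction = edit_enabled_fraction,
              decoy_repeat_prob = decoy_repeat_prob,
              background_gq_per_gene = background_gq_per_gene,
              flank_bp = as.integer(flank_bp))
  rng <- function(x) length(x) == 2L && !anyNA(x) && x[1] <= x[2] && x[1] >= 0L
  if (is.na(cfg$seed)) config_error("seed must be an integer")
  if (is.na(cfg$n_genes) || cfg$n_genes < 1L) {
    config_error("n_genes must be >= 1")
  }
  for (f in c("isoforms_per_gene", "exons_per_transcript", "exon_len",
              "intron_len", "gq_distance", "alu_overlap")) {
    if (!rng(cfg[[f]])) config_error(sprintf("%s must be a range (lo, hi)", f))
  }
  if (cfg$exons_per_transcript[1] < 3L) {
    config_error("exons_per_transcript minimum must be >= 3")
  }
  if (cfg$isoforms_per_gene[1] < 1L) {
    config_error("isoforms_per_gene minimum must be >= 1")
  }
  if (cfg$exon_len[1] < 10L) config_error("exon_len minimum must be >= 10")
  if (cfg$intron_len[1] < 60L) {
    config_error("intron_len minimum must be >= 60 (room for planted elements)")
  }
  if (cfg$gc_fraction < 0 || cfg$gc_fraction > 1) {
    config_error("gc_fraction must be in [0, 1]")
  }
  if (!setequal(names(cfg$class_mixture), positional_classes)) {
    config_error("class_mixture must name the four positional classes")
  }
  if (abs(sum(cfg$class_mixture) - 1) > 1e-8) {
    config_error("class_mixture must sum to 1")
  }
  for (f in c("gq_prob", "alu_prob", "splice_prob", "edit_enabled_fraction",
              "decoy_repeat_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      config_error(sprintf("%s must be a probability", f))
    }
  }
  if (cfg$alu_overlap[1] < 1L) config_error("alu_overlap minimum must be >= 1")
  if (cfg$flank_bp < 60L) config_error("flank_bp must be >= 60")
  # The longest planted motif is 8 G + 3 loops of <= 10 nt = 38 nt; it must
  # fit inside the window at the largest planted distance.
  if (cfg$gq_distance[2] + 38L > cfg$flank_bp + 1L) {
    config_error("gq_distance[2] + 38 must be <= flank_bp + 1 so planted motifs fit the window")
  }
  if (cfg$gq_distance[1] < 2L) {
    config_error("gq_distance minimum must be >= 2")
  }
  structure(cfg, class = "synthetic_config")
}

# Uniform integer in [lo, hi].
rint <- function(lo, hi, n = 1L) {
  if (hi < lo) config_error("empty integer range")
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Background sequence with neither GG nor CC anywhere.
gg_free_seq <- function(len, gc_fraction) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  s <- paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  m <- gregexpr("GG|CC", s)[[1]]
  if (m[1] != -1L) {
    # Replacing the second base of each (non-overlapping) GG/CC with A or T
    # removes every such pair and cannot create a new one.
    cv <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- as.integer(m) + 1L
    cv[idx] <- sample(c("A", "T"), length(idx), replace = TRUE)
    s <- paste(cv, collapse = "")
  }
  s
}

# A quadruplex motif with two-G runs and {A,T} loops: exactly one canonical
# hit, no G/C on the opposite strand.
make_motif <- function(n_loops = 3L) {
  loops <- vapply(seq_len(n_loops), function(i) {
    paste(sample(c("A", "T"), rint(1L, 10L), replace = TRUE), collapse = "")
  }, character(1))
  paste0("GG", paste0(loops, "GG", collapse = ""))
}

# Defective motif completed by editing: three GG runs plus a trailing "GA";
# substituting the final A by G completes the fourth run.
make_edit_enabled_construct <- function() {
  loops <- vapply(1:3, function(i) {
    paste(sample(c("A", "T"), rint(1L, 10L), replace = TRUE), collapse = "")
  }, character(1))
  paste0("GG", loops[1], "GG", loops[2], "GG", loops[3], "GA")
}

# Does [s, e) with margin m clash with any reserved interval?
clashes <- function(reserved, s, e, margin = 12L) {
  if (length(reserved) == 0) return(FALSE)
  any(vapply(reserved, function(iv) {
    s - margin < iv[2] && iv[1] < e + margin
  }, logical(1)))
}

#' Generate a synthetic dataset with planted truth
#'
#' Produces a genome, transcript models, repeat annotations and edit sites
#' whose annotation ground truth is known by construction (see
#' [synthetic_config()] for the planting model). Deterministic given the
#' configuration.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `transcripts.gtf`, `repeats.bed`, `edits.tsv` and `truth.tsv` there.
#' @return List with `genome` (named character vector), `transcripts`,
#'   `repeats`, `edits`, `truth` (data frames) and `config`; when `out_dir`
#'   is given, also `files` (named paths).
#' @export
simulate_dataset <- function(config = synthetic_config(), out_dir = NULL) {
  if (!inherits(config, "synthetic_config")) {
    config_error("config must be created with synthetic_config()")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  pad <- config$flank_bp + 200L
  genome <- character(config$n_genes)
  contig_names <- sprintf("ctg%05d", seq_len(config$n_genes))
  tx_rows <- list()
  rep_rows <- list()
  edit_rows <- list()
  truth_rows <- list()

  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("G%05d", g)
    ctg <- contig_names[g]
    strand <- sample(c("+", "-"), 1L)
    k <- rint(config$exons_per_transcript[1], config$exons_per_transcript[2])
    elens <- rint(config$exon_len[1], config$exon_len[2], k)
    ilens <- rint(config$intron_len[1], config$intron_len[2], k - 1L)
    estarts <- integer(k)
    estarts[1] <- pad
    if (k > 1L) {
      for (j in 2:k) estarts[j] <- estarts[j - 1L] + elens[j - 1L] + ilens[j - 1L]
    }
    eends <- estarts + elens
    contig_len <- eends[k] + pad

    # --- choose class and edit position -----------------------------------
    cls <- sample(positional_classes, 1L,
                  prob = config$class_mixture[positional_classes])
    ori_first <- if (strand == "+") 1L else k
    ori_last <- if (strand == "+") k else 1L
    exon_j <- switch(cls,
      first_exon = ori_first,
      last_exon = ori_last,
      internal_exon = {
        internals <- setdiff(seq_len(k), c(ori_first, ori_last))
        if (length(internals) == 1L) internals else sample(internals, 1L)
      },
      non_exonic = NA_integer_
    )
    if (is.na(exon_j)) {
      intr <- if (k == 2L) 1L else sample.int(k - 1L, 1L)
      p <- rint(eends[intr] + 25L, estarts[intr + 1L] - 25L)
    } else {
      p <- rint(estarts[exon_j] + 1L, eends[exon_j] - 2L)
    }

    # --- plant elements ---------------------------------------------------
    reserved <- list(c(p - 1L, p + 2L))
    plants <- list() # list of (start, content)

    ee <- stats::runif(1) < config$edit_enabled_fraction
    ee_len <- 0L
    if (ee) {
      con <- make_edit_enabled_construct()
      ee_len <- nchar(con)
      if (strand == "+") {
        s0 <- p - ee_len + 1L
        plants[[length(plants) + 1L]] <- list(start = s0, content = con)
        reserved[[length(reserved) + 1L]] <- c(s0, s0 + ee_len)
      } else {
        s0 <- p
        plants[[length(plants) + 1L]] <- list(start = s0, content = revcomp(con))
        reserved[[length(reserved) + 1L]] <- c(s0, s0 + ee_len)
      }
    }

    gq <- stats::runif(1) < config$gq_prob
    gq_d <- NA_integer_
    if (gq) {
      motif <- make_motif()
      mlen <- nchar(motif)
      sign_choices <- if (!ee) sample(c(1L, -1L)) else if (strand == "+") 1L else -1L
      placed <- FALSE
      for (sgn in sign_choices) {
        lo <- if (sgn > 0L) max(config$gq_distance[1], ee_len + 2L) else
          max(config$gq_distance[1], mlen + 2L)
        hi <- if (sgn > 0L) min(config$gq_distance[2],
                                config$flank_bp + 1L - mlen) else
          config$gq_distance[2]
        if (hi < lo) next
        for (try in 1:50) {
          d <- sgn * rint(lo, hi)
          s0 <- p + d
          if (s0 < 2L || s0 + mlen > contig_len - 2L) next
          if (clashes(reserved, s0, s0 + mlen)) next
          content <- if (strand == "+") motif else revcomp(motif)
          plants[[length(plants) + 1L]] <- list(start = s0, content = content)
          reserved[[length(reserved) + 1L]] <- c(s0, s0 + mlen)
          gq_d <- d
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (!placed) gq <- FALSE
    }

    # Extra motifs independent of the edit (null-calibration mode).
    if (config$background_gq_per_gene > 0) {
      n_bg <- stats::rpois(1L, config$background_gq_per_gene)
      for (b in seq_len(n_bg)) {
        motif <- make_motif()
        mlen <- nchar(motif)
        for (try in 1:50) {
          s0 <- rint(50L, contig_len - 50L - mlen)
          if (clashes(reserved, s0, s0 + mlen)) next
          content <- if (strand == "+") motif else revcomp(motif)
          plants[[length(plants) + 1L]] <- list(start = s0, content = content)
          reserved[[length(reserved) + 1L]] <- c(s0, s0 + mlen)
          break
        }
      }
    }

    # --- sequence ---------------------------------------------------------
    seq <- gg_free_seq(contig_len, config$gc_fraction)
    for (pl in plants) {
      substr(seq, pl$start + 1L, pl$start + nchar(pl$content)) <- pl$content
    }
    in_plant <- function(pos) {
      any(vapply(plants, function(pl) {
        pos >= pl$start && pos < pl$start + nchar(pl$content)
      }, logical(1)))
    }
    # Force A/T at element boundaries and around the edit: a G would extend
    # a plus-strand run, a C would extend a minus-strand run.
    guard <- unique(unlist(lapply(plants, function(pl) {
      c(pl$start - 1L, pl$start + nchar(pl$content))
    })))
    guard <- unique(c(guard, p - 1L, p + 1L))
    for (q in guard) {
      if (q < 0L || q >= contig_len || in_plant(q)) next
      if (substr(seq, q + 1L, q + 1L) %in% c("G", "C")) {
        substr(seq, q + 1L, q + 1L) <- "A"
      }
    }
    # The edited base itself.
    if (!ee) {
      substr(seq, p + 1L, p + 1L) <- if (strand == "+") "A" else "T"
    }
    genome[g] <- seq

    # --- repeats ----------------------------------------------------------
    alu_bp <- 0L
    if (!is.na(exon_j) && stats::runif(1) < config$alu_prob) {
      o <- min(rint(config$alu_overlap[1], config$alu_overlap[2]),
               elens[exon_j])
      ext <- rint(20L, 100L)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        contig = ctg, start = max(0L, estarts[exon_j] - ext),
        end = estarts[exon_j] + o, strand = strand, family = "AluSyn",
        stringsAsFactors = FALSE
      )
      alu_bp <- o
    }
    if (!is.na(exon_j) && stats::runif(1) < config$decoy_repeat_prob) {
      o2 <- min(rint(5L, 50L), elens[exon_j])
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        contig = ctg, start = eends[exon_j] - o2,
        end = min(contig_len, eends[exon_j] + 30L), strand = strand,
        family = "L1Syn", stringsAsFactors = FALSE
      )
    }

    # --- isoforms ---------------------------------------------------------
    exon_df <- function(tx, idx) {
      data.frame(transcript_id = tx, gene_id = gene_id, contig = ctg,
                 start = estarts[idx], end = eends[idx], strand = strand,
                 stringsAsFactors = FALSE)
    }
    tx_rows[[length(tx_rows) + 1L]] <- exon_df(paste0(gene_id, ".t1"),
                                               seq_len(k))
    n_iso <- rint(config$isoforms_per_gene[1], config$isoforms_per_gene[2])
    skippable <- setdiff(2:(k - 1L), exon_j)
    for (ii in seq_len(n_iso - 1L)) {
      tx <- sprintf("%s.t%d", gene_id, ii + 1L)
      keep <- seq_len(k)
      if (length(skippable) > 0) {
        drop1 <- if (length(skippable) == 1L) skippable else
          sample(skippable, 1L)
        keep <- setdiff(keep, drop1)
      }
      tx_rows[[length(tx_rows) + 1L]] <- exon_df(tx, keep)
    }
    splice <- FALSE
    if (!is.na(exon_j) && gq && stats::runif(1) < config$splice_prob) {
      tx <- paste0(gene_id, ".sk")
      if (exon_j == 1L) {
        aux <- data.frame(transcript_id = tx, gene_id = gene_id, contig = ctg,
                          start = 150L, end = 230L, strand = strand,
                          stringsAsFactors = FALSE)
        tx_rows[[length(tx_rows) + 1L]] <- rbind(aux, exon_df(tx, 2L))
      } else if (exon_j == k) {
        aux <- data.frame(transcript_id = tx, gene_id = gene_id, contig = ctg,
                          start = eends[k] + 150L, end = eends[k] + 230L,
                          strand = strand, stringsAsFactors = FALSE)
        tx_rows[[length(tx_rows) + 1L]] <- rbind(exon_df(tx, k - 1L), aux)
      } else {
        tx_rows[[length(tx_rows) + 1L]] <- exon_df(tx, c(exon_j - 1L,
                                                         exon_j + 1L))
      }
      splice <- TRUE
    }

    edit_rows[[length(edit_rows) + 1L]] <- data.frame(
      contig = ctg, position = p, strand = strand, gene_id = gene_id,
      edit_class = "nonsynonymous", stringsAsFactors = FALSE
    )
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      edit_id = sprintf("E%05d", g), contig = ctg, position = p,
      strand = strand, gene_id = gene_id, class = cls,
      gq_planted = gq, gq_distance = gq_d, alu_overlap = alu_bp,
      splice_planted = splice, edit_enabled = ee, stringsAsFactors = FALSE
    )
  }

  names(genome) <- contig_names
  transcripts <- do.call(rbind, tx_rows)
  transcripts <- transcripts[order(transcripts$transcript_id,
                                   transcripts$start), , drop = FALSE]
  rownames(transcripts) <- NULL
  repeats <- if (length(rep_rows) == 0) {
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), family = character(0))
  } else {
    do.call(rbind, rep_rows)
  }
  edits <- do.call(rbind, edit_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(repeats) <- rownames(edits) <- rownames(truth) <- NULL

  out <- list(genome = genome, transcripts = transcripts, repeats = repeats,
              edits = edits, truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      genome = file.path(out_dir, "genome.fa"),
      transcripts = file.path(out_dir, "transcripts.gtf"),
      repeats = file.path(out_dir, "repeats.bed"),
      edits = file.path(out_dir, "edits.tsv"),
      truth = file.path(out_dir, "truth.tsv")
    )
    write_fasta(genome, files[["genome"]])
    write_gtf(transcripts, files[["transcripts"]])
    rb <- repeats
    rb$name <- rb$family
    write_bed(rb, files[["repeats"]])
    write_edits(edits, files[["edits"]])
    utils::write.table(truth, files[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    out$files <- files
  }
  out
}

#' Locate the tiny worked-example fixture
#'
#' A hand-built genome of under 5 kb shipped with the package: one gene with
#' two isoforms, one edit with a planted quadruplex motif 50 bp downstream,
#' one Alu-like repeat overlapping an edited exon by 50 bp, one edit that
#' completes a quadruplex upon substitution, and one deliberately invalid
#' edit (non-A base) that triggers exactly one validation warning. The
#' expected annotation table is checked in alongside.
#'
#' @return Named list of file paths: `genome`, `transcripts`, `repeats`,
#'   `edits`, `expected_annotation`.
#' @export
worked_example <- function() {
  dir <- system.file("extdata", "worked_example", package = "quadedit")
  if (!nzchar(dir)) lookup_error("worked_example fixture not found")
  list(
    genome = file.path(dir, "genome.fa"),
    transcripts = file.path(dir, "transcripts.gtf"),
    repeats = file.path(dir, "repeats.bed"),
    edits = file.path(dir, "edits.tsv"),
    expected_annotation = file.path(dir, "expected_annotation.tsv")
  )
}
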
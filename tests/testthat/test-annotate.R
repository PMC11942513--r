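# A small hand-built gene used by several blocks: plus strand, three exons.
toy_gene <- function() {
  tx <- function(id, starts, ends, strand = "+") {
    data.frame(transcript_id = id, gene_id = "G1", contig = "c1",
               start = starts, end = ends, strand = strand,
               stringsAsFactors = FALSE)
  }
  rbind(
    tx("t1", c(100L, 300L, 500L), c(200L, 400L, 600L)),
    tx("t2", c(100L, 500L), c(200L, 600L)) # skips the middle exon
  )
}

test_that("windowed quadruplex search respects strand and window bounds", {
  motif <- "GGTGGTGGTGG"
  # plant a plus-strand motif 50 bp 3' of a plus-strand edit at 300
  seq <- plant_at(random_seq_fixed(560, 77), 350L, motif)
  genome <- c(c1 = seq)
  edit <- list(contig = "c1", position = 300L, strand = "+")
  res <- gq_near_edit(edit, genome)
  expect_true(res$found)
  expect_equal(res$min_distance_bp, 50L)
  expect_true(all(res$hits$strand == "+"))

  # motif only on the opposite strand: not found under the same-strand rule
  seqm <- plant_at(random_seq_fixed(560, 79), 350L, revcomp(motif))
  res <- gq_near_edit(list(contig = "c1", position = 300L, strand = "+"),
                      c(c1 = seqm))
  expect_false(res$found)
  res <- gq_near_edit(list(contig = "c1", position = 300L, strand = "+"),
                      c(c1 = seqm),
                      window = window_config(same_strand_only = FALSE))
  expect_true(res$found)
  expect_equal(res$hits$strand, "-")

  # boundary clamp: edit near the contig start
  res <- gq_near_edit(list(contig = "c1", position = 10L, strand = "+"),
                      c(c1 = random_seq_fixed(500, 81)))
  expect_false(res$found) # and no error
  expect_error(gq_near_edit(list(contig = "nope", position = 1L, strand = "+"),
                            genome),
               "nope", class = "quadedit_lookup_error")
})

test_that("windowed search flags agree with an oracle rescan of extracted windows", {
  set.seed(500)
  flank <- 200L
  for (i in 1:120) {
    plant <- runif(1) < 0.5
    strand <- sample(c("+", "-"), 1)
    seq <- random_seq(900, runif(1, 0.35, 0.6))
    # remove GG/CC so the background cannot match on either strand
    seq <- gsub("GG", "GA", seq, fixed = TRUE)
    seq <- gsub("CC", "CA", seq, fixed = TRUE)
    p <- 450L
    d <- NA
    if (plant) {
      motif <- "GGTAGGTTAGGATGG"
      d <- sample(c(-150:-40, 20:150), 1)
      s0 <- p + d
      content <- if (strand == "+") motif else revcomp(motif)
      seq <- plant_at(seq, s0, content)
    }
    res <- gq_near_edit(list(contig = "c1", position = p, strand = strand),
                        c(c1 = seq))
    # oracle: rescan the extracted window on the edit strand directly
    win <- substr(seq, p - flank + 1L, p + flank + 1L)
    wseq <- if (strand == "+") win else revcomp(win)
    expect_equal(res$found, nrow(oracle_scan_gq(wseq)) > 0,
                 info = sprintf("case %d", i))
    if (plant) expect_equal(res$min_distance_bp, d)
  }
})

test_that("positional classification follows transcript orientation", {
  tr <- toy_gene()
  cls <- classify_edit(list(contig = "c1", position = 150L, gene_id = "G1"), tr)
  expect_equal(cls$aggregate, "first_exon")
  cls <- classify_edit(list(contig = "c1", position = 350L, gene_id = "G1"), tr)
  # middle exon of t1, absent from t2
  expect_equal(cls$per_transcript$class, c("internal_exon", "non_exonic"))
  expect_equal(cls$aggregate, "internal_exon")
  cls <- classify_edit(list(contig = "c1", position = 550L, gene_id = "G1"), tr)
  expect_equal(cls$aggregate, "last_exon")
  # intronic everywhere
  cls <- classify_edit(list(contig = "c1", position = 250L, gene_id = "G1"), tr)
  expect_equal(cls$aggregate, "non_exonic")

  # minus strand: the genomically first exon is the transcript's last
  trm <- toy_gene()
  trm$strand <- "-"
  cls <- classify_edit(list(contig = "c1", position = 150L, gene_id = "G1"), trm)
  expect_equal(cls$aggregate, "last_exon")
  cls <- classify_edit(list(contig = "c1", position = 550L, gene_id = "G1"), trm)
  expect_equal(cls$per_transcript$class[1], "first_exon")

  # single-exon transcript classifies as last_exon
  single <- data.frame(transcript_id = "s1", gene_id = "G2", contig = "c1",
                       start = 0L, end = 100L, strand = "+",
                       stringsAsFactors = FALSE)
  cls <- classify_edit(list(contig = "c1", position = 50L, gene_id = "G2"),
                       single)
  expect_equal(cls$aggregate, "last_exon")
})

test_that("exon-repeat overlaps match interval arithmetic and the all-pairs oracle", {
  ex <- data.frame(contig = "c1", start = 100L, end = 200L)
  rp <- data.frame(contig = "c1", start = 150L, end = 400L, strand = "+",
                   family = "AluSx", stringsAsFactors = FALSE)
  ov <- exon_repeat_overlaps(ex, rp)
  expect_equal(ov$records$overlap_bp, 50L)
  # disjoint
  ov <- exon_repeat_overlaps(ex, transform(rp, start = 300L))
  expect_equal(nrow(ov$records), 0L)
  expect_equal(ov$summary$n_exons, 0L)

  # summary arithmetic on the stated values
  ex3 <- data.frame(contig = "c1", start = c(0L, 1000L, 2000L),
                    end = c(400L, 1400L, 2400L))
  rp3 <- data.frame(contig = "c1",
                    start = c(0L, 1000L, 2000L),
                    end = c(5L, 1122L, 2322L),
                    strand = "+", family = "AluY", stringsAsFactors = FALSE)
  ov <- exon_repeat_overlaps(ex3, rp3)
  expect_equal(sort(ov$records$overlap_bp), c(5L, 122L, 322L))
  expect_equal(ov$summary$median, 122)
  expect_equal(round(ov$summary$mean, 2), 149.67)

  set.seed(66)
  for (i in 1:40) {
    ne <- sample(0:15, 1)
    nr <- sample(0:15, 1)
    mk <- function(n) {
      s <- sample.int(500, n, replace = TRUE)
      data.frame(contig = sample(c("c1", "c2"), n, replace = TRUE),
                 start = s, end = s + sample.int(80, n, replace = TRUE))
    }
    ex <- mk(ne)
    rp <- mk(nr)
    rp$strand <- rep("+", nrow(rp))
    rp$family <- rep("AluSyn", nrow(rp))
    got <- exon_repeat_overlaps(ex, rp)$records
    want <- oracle_overlaps(ex, rp)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got[, c("exon_idx", "repeat_idx", "overlap_bp")], want,
                   ignore_attr = TRUE)
    }
    # overlap symmetry: transposing the arguments preserves the pair set
    rp2 <- ex
    rp2$strand <- rep("+", nrow(rp2))
    rp2$family <- rep("AluSyn", nrow(rp2))
    tr <- exon_repeat_overlaps(rp[, c("contig", "start", "end")], rp2)$records
    expect_setequal(paste(got$exon_idx, got$repeat_idx),
                    paste(tr$repeat_idx, tr$exon_idx))
  }
})

test_that("splice association is the isoform-intron overlap criterion", {
  tr <- toy_gene()
  # t2's intron [200, 500) spans t1's middle exon
  expect_true(splice_association(tr, list(contig = "c1", start = 300L,
                                          end = 400L)))
  # shared exon at identical coordinates: no other isoform's intron spans it
  expect_false(splice_association(tr, list(contig = "c1", start = 100L,
                                           end = 200L)))
  # single-isoform gene
  t1 <- tr[tr$transcript_id == "t1", ]
  expect_false(splice_association(t1, list(contig = "c1", start = 300L,
                                           end = 400L)))
  expect_error(splice_association(tr, list(contig = "c1", start = 1L,
                                           end = 2L)),
               class = "quadedit_validation_error")
})

test_that("annotate_all handles empty input, is deterministic, and flags bad records", {
  sim <- simulate_dataset(synthetic_config(seed = 21, n_genes = 25))
  expect_equal(nrow(annotate_all(sim$edits[0, ], sim$genome, sim$transcripts,
                                 sim$repeats)), 0L)
  a1 <- annotate_all(sim$edits, sim$genome, sim$transcripts, sim$repeats)
  a2 <- annotate_all(sim$edits, sim$genome, sim$transcripts, sim$repeats)
  expect_identical(a1, a2)
  # every edit gets exactly one aggregate class
  expect_true(all(a1$aggregate_class %in%
                    c("first_exon", "last_exon", "internal_exon", "non_exonic")))
  # window containment: |min distance| <= flank
  expect_true(all(abs(a1$gq_min_distance_bp[a1$gq_found]) <= 200L))

  # a deliberately corrupted record is excluded, not fatal
  ed <- sim$edits
  want <- if (ed$strand[3] == "+") "A" else "T"
  pad <- strsplit(substr(sim$genome[[ed$contig[3]]], 1, 50), "")[[1]]
  ed$position[3] <- which(pad != want)[1] - 1L
  a3 <- suppressWarnings(annotate_all(ed, sim$genome, sim$transcripts,
                                      sim$repeats))
  expect_true(any(a3$excluded))
  expect_true(all(is.na(a3$aggregate_class[a3$excluded])))
  expect_error(
    suppressWarnings(annotate_all(ed, sim$genome, sim$transcripts,
                                  sim$repeats, strict = TRUE)),
    class = "quadedit_validation_error")
})

test_that("annotations are invariant under genome mirroring", {
  sim <- simulate_dataset(synthetic_config(seed = 33, n_genes = 20))
  ann <- annotate_all(sim$edits, sim$genome, sim$transcripts, sim$repeats)
  mir <- mirror_dataset(sim)
  ann_m <- annotate_all(mir$edits, mir$genome, mir$transcripts, mir$repeats)
  cols <- c("aggregate_class", "gq_found", "alu_overlap_bp",
            "splice_associated", "edit_enabled", "excluded")
  expect_identical(ann_m[, cols], ann[, cols])
  # the reported minimum distance is a mirror image of an interval start;
  # its magnitude stays within the window on both sides
  expect_true(all(abs(ann_m$gq_min_distance_bp[ann_m$gq_found]) <= 200L))
})
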
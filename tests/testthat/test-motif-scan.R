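test_that("grammar matches and decompositions on canonical examples", {
  h <- scan_gq("GGTGGTGGTGG")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 11L))
  expect_equal(unname(h$runs[[1]][, 1]), c(0L, 3L, 6L, 9L))
  expect_equal(unname(h$runs[[1]][, 2]), c(2L, 5L, 8L, 11L))

  # only three runs
  expect_equal(nrow(scan_gq("GGTTGGTTGG")), 0L)
  # a single long run is one run, not four
  expect_equal(nrow(scan_gq("GGGGGGGG")), 0L)
  # N never matches G, but is a legal loop base
  expect_equal(nrow(scan_gq("GGNGGNGGNGG")), 1L)
  expect_equal(nrow(scan_gq("GGTGGTGGTGNG")), 0L) # N splits the final run

  # longer first run admits one extra (suffix) match start
  h <- scan_gq("GGGTGGTGGTGG")
  expect_equal(h$start, c(0L, 1L))
  expect_equal(h$end, c(12L, 12L))
})

test_that("pattern parameters are validated and presets differ", {
  expect_error(gq_pattern(min_run_length = 1), class = "quadedit_config_error")
  expect_error(gq_pattern(loop_min = 5, loop_max = 2),
               class = "quadedit_config_error")
  expect_error(scan_gq("ACGT", pattern = list(min_run_length = 2)),
               class = "quadedit_config_error")
  # two-tetrad motif is found by the rGQ grammar but not the strict dGQ one
  s <- "GGTGGTGGTGG"
  expect_equal(nrow(scan_gq(s, gq_preset("rgq"))), 1L)
  expect_equal(nrow(scan_gq(s, gq_preset("dgq_strict"))), 0L)
  expect_equal(nrow(scan_gq("GGGTGGGTGGGTGGG", gq_preset("dgq_strict"))), 1L)
})

test_that("scanner equals brute-force grammar enumeration on random sequences", {
  set.seed(421)
  for (i in 1:300) {
    s <- random_seq(sample(200:600, 1), runif(1, 0.3, 0.7))
    expect_identical(interval_key(scan_gq(s)),
                     interval_key(oracle_scan_gq(s)),
                     info = sprintf("sequence %d", i))
  }
})

test_that("every returned decomposition re-checks against the grammar", {
  set.seed(77)
  for (i in 1:40) {
    s <- random_seq(500, 0.65)
    h <- scan_gq(s)
    for (j in seq_len(nrow(h))) {
      expect_true(isTRUE(check_witness(s, h[j, , drop = FALSE], gq_pattern())))
    }
  }
})

test_that("genome scanning is strand-symmetric under reverse complement", {
  set.seed(9)
  genome <- c(c1 = random_seq(600, 0.6), c2 = random_seq(400, 0.55))
  mirror <- vapply(genome, revcomp, character(1))
  h <- scan_gq_genome(genome, strands = "both")
  hm <- scan_gq_genome(mirror, strands = "both")
  L <- nchar(genome)
  key <- function(df, lens) {
    sort(paste(df$contig, df$start, df$end, df$strand))
  }
  # map mirror hits back into original coordinates
  hm2 <- hm
  hm2$start <- L[hm$contig] - hm$end
  hm2$end <- L[hm$contig] - hm$start
  hm2$strand <- ifelse(hm$strand == "+", "-", "+")
  expect_setequal(paste(h$contig, h$start, h$end, h$strand),
                  paste(hm2$contig, hm2$start, hm2$end, hm2$strand))
  # plus-strand identity mapping: a planted motif is found where planted
  g2 <- c(cX = paste0(strrep("A", 100), "GGTGGTGGTGG", strrep("A", 100)))
  hp <- scan_gq_genome(g2, strands = "plus")
  expect_equal(hp$start, 100L)
  expect_equal(hp$end, 111L)
  expect_equal(hp$strand, "+")
  hm3 <- scan_gq_genome(c(cX = revcomp(g2[["cX"]])), strands = "minus")
  expect_equal(hm3$start, 100L)
  expect_equal(hm3$end, 111L)
  expect_equal(hm3$strand, "-")
  expect_equal(nrow(scan_gq_genome(c(a = strrep("A", 300)))), 0L)
})

test_that("relaxing the grammar never loses matches", {
  set.seed(31)
  for (i in 1:30) {
    s <- random_seq(300, 0.65)
    strict <- scan_gq(s, gq_pattern(loop_max = 6))
    relaxed <- scan_gq(s, gq_pattern(loop_max = 10))
    expect_true(all(strict$start %in% relaxed$start))
    strict3 <- scan_gq(s, gq_pattern(min_run_length = 3))
    relaxed2 <- scan_gq(s, gq_pattern(min_run_length = 2))
    expect_true(all(strict3$start %in% relaxed2$start))
    # exhaustive mode: interval sets are monotone
    ex_strict <- scan_gq(s, gq_pattern(loop_max = 6), policy = "exhaustive")
    ex_rel <- scan_gq(s, gq_pattern(loop_max = 10), policy = "exhaustive")
    expect_true(all(interval_key(ex_strict) %in% interval_key(ex_rel)))
  }
})

test_that("exhaustive enumeration is a superset of the canonical policy", {
  set.seed(13)
  for (i in 1:20) {
    s <- random_seq(250, 0.65)
    can <- scan_gq(s)
    ex <- scan_gq(s, policy = "exhaustive")
    expect_true(all(interval_key(can) %in% interval_key(ex)))
  }
  # run splitting finds matches the maximal-run policy rejects
  s <- "GGGGGTTGGTTGG" # 5-G run can serve as GG + G-loop + GG
  expect_equal(nrow(scan_gq(s)), 0L)
  ex <- scan_gq(s, policy = "exhaustive")
  expect_gt(nrow(ex), 0L)
})

test_that("z-tract scanner finds maximal alternating purine/pyrimidine tracts", {
  h <- scan_z_tract("GCGCGCGCGC", min_dinucleotides = 5)
  expect_equal(c(h$start, h$end), c(0L, 10L))
  h <- scan_z_tract("CACACACA", min_dinucleotides = 4)
  expect_equal(c(h$start, h$end), c(0L, 8L))
  expect_equal(nrow(scan_z_tract("GGGG", 2)), 0L)
  # N breaks a tract
  expect_equal(nrow(scan_z_tract("GCGCNGCGC", 4)), 0L)
  expect_error(scan_z_tract("GCGC", 1), class = "quadedit_config_error")

  set.seed(5)
  for (i in 1:20) {
    s <- random_seq(400, 0.5)
    h <- scan_z_tract(s, 3)
    for (j in seq_len(nrow(h))) {
      sub <- substr(s, h$start[j] + 1L, h$end[j])
      cls <- ifelse(strsplit(sub, "")[[1]] %in% c("A", "G"), "R", "Y")
      expect_true(all(cls[-1] != cls[-length(cls)]))
      expect_gte(nchar(sub), 6L)
    }
  }
})

test_that("edit-enabled rescan reports exactly the motifs the substitution completes", {
  r <- edit_enabled_gq("GGTGGTGGTGA", 10)
  expect_true(r[[1]]$ok)
  expect_equal(nrow(r[[1]]$new_hits), 1L)
  expect_equal(c(r[[1]]$new_hits$start, r[[1]]$new_hits$end), c(0L, 11L))

  # motif pre-exists: editing an A in the flanking sequence creates nothing
  r <- edit_enabled_gq("GGTGGTGGTGGTA", 12)
  expect_true(r[[1]]$ok)
  expect_equal(nrow(r[[1]]$new_hits), 0L)
  # but an A directly extending the final run does yield a new, longer hit
  r <- edit_enabled_gq("GGTGGTGGTGGA", 11)
  expect_equal(nrow(r[[1]]$new_hits), 1L)
  expect_equal(r[[1]]$new_hits$end, 12L)

  # non-A offset: per-offset validation error, others processed
  r <- edit_enabled_gq("GGTGGTGGTGA", c(2, 10))
  expect_false(r[[1]]$ok)
  expect_match(r[[1]]$message, "expected 'A'")
  expect_true(r[[2]]$ok)
  expect_equal(nrow(r[[2]]$new_hits), 1L)
})

test_that("reverting the substitution removes every reported new hit", {
  set.seed(202)
  for (i in 1:60) {
    flank1 <- random_seq(sample(20:60, 1), 0.4)
    flank2 <- random_seq(sample(20:60, 1), 0.4)
    loops <- replicate(3, paste(sample(c("A", "T"), sample(1:10, 1),
                                       replace = TRUE), collapse = ""))
    core <- paste0("GG", loops[1], "GG", loops[2], "GG", loops[3], "GA")
    s <- paste0(flank1, core, flank2)
    off <- nchar(flank1) + nchar(core) - 1L
    res <- edit_enabled_gq(s, off)[[1]]
    expect_true(res$ok)
    for (j in seq_len(nrow(res$new_hits))) {
      expect_true(res$new_hits$start[j] <= off && res$new_hits$end[j] > off)
      # revert: the hit must be absent from the original scan
      orig <- scan_gq(s)
      expect_false(any(orig$start == res$new_hits$start[j] &
                         orig$end == res$new_hits$end[j]))
    }
  }
})
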
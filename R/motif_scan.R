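# Quadruplex motif scanner.
#
# A match under the grammar is R1 L1 R2 L2 ... Rn: n runs of >= r consecutive
# G separated by loops whose lengths lie in [loop_min, loop_max]. Loop bases
# are unrestricted (they may contain G or N); N never extends a G-run.
#
# Enumeration policy (default, "canonical"): runs are maximal within the
# match, i.e. no loop character adjacent to a run is a G. Consequently every
# internal run and the final run is a full maximal G-run of the sequence,
# while the first run may be the suffix of a maximal run (the G before the
# match start lies outside the match). One hit is reported per distinct match
# start: the shortest-loop, earliest-run decomposition, with the final run
# taken greedily to its full extent. "exhaustive" drops the maximality
# requirement and reports every distinct (start, end) that admits any
# decomposition, which is the superset oracles enumerate against.

# Maximal G-runs of a sequence, 0-based half-open.
g_runs <- function(seq) {
  m <- gregexpr("G+", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0), len = integer(0)))
  }
  st <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(start = st, end = st + len, len = len)
}

assert_normalized_seq <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) {
    validation_error("'seq' must be a single character string")
  }
  if (grepl("[^ACGTN]", seq)) {
    validation_error("sequence contains characters outside {A,C,G,T,N}; normalize first")
  }
  seq
}

#' Scan a sequence for quadruplex motif matches
#'
#' Finds matches of the quadruplex grammar (see [gq_pattern()]) in a literal
#' nucleotide string. The caller supplies the reverse complement when the
#' minus strand is to be searched; [scan_gq_genome()] does this mapping.
#'
#' @param seq Normalized nucleotide string over `{A,C,G,T,N}`.
#' @param pattern A [gq_pattern()].
#' @param strand_label Strand recorded on the hits (`"+"`, `"-"` or `"."`);
#'   purely a label, the scan is always over the literal string.
#' @param policy `"canonical"` (one hit per match start, maximal runs) or
#'   `"exhaustive"` (every decomposable substring; used by oracle tests).
#' @return A data frame of hits sorted by start: `start`, `end` (0-based
#'   half-open offsets into `seq`), `strand`, `matched_sequence`, and list
#'   columns `runs` and `loops` holding the decomposition as two-column
#'   (start, end) integer matrices.
#' @examples
#' scan_gq("GGTGGTGGTGG")
#' @export
scan_gq <- function(seq, pattern = gq_pattern(), strand_label = ".",
                    policy = c("canonical", "exhaustive")) {
  assert_pattern(pattern)
  policy <- match.arg(policy)
  assert_normalized_seq(seq)
  if (!strand_label %in% c("+", "-", ".")) {
    config_error("strand_label must be one of '+', '-', '.'")
  }
  if (nchar(seq) < gq_min_match_length(pattern)) return(empty_hits())
  hits <- if (policy == "canonical") {
    scan_gq_canonical(seq, pattern)
  } else {
    scan_gq_exhaustive(seq, pattern)
  }
  if (nrow(hits) > 0) hits$strand <- strand_label
  hits
}

# Canonical policy. Because the chain of full runs following a given maximal
# run does not depend on where inside that run the match starts, the search
# is done once per candidate run, then expanded to every admissible suffix
# start.
scan_gq_canonical <- function(seq, pattern) {
  r <- pattern$min_run_length
  n <- pattern$n_runs
  gap_min <- max(pattern$loop_min, 1L) # maximality forbids zero-length loops
  gap_max <- pattern$loop_max
  cand <- g_runs(seq)
  cand <- cand[cand$len >= r, , drop = FALSE]
  nc <- nrow(cand)
  if (nc < n) return(empty_hits())
  fail <- matrix(FALSE, nrow = nc, ncol = n + 1L)

  # Earliest-run chain of runs k..n after chosen run i, or NULL.
  solve <- function(i, k) {
    if (k > n) return(integer(0))
    if (fail[i, k]) return(NULL)
    lo <- cand$end[i] + gap_min
    hi <- cand$end[i] + gap_max
    js <- which(cand$start >= lo & cand$start <= hi)
    for (j in js) {
      rest <- solve(j, k + 1L)
      if (!is.null(rest)) return(c(j, rest))
    }
    fail[i, k] <<- TRUE
    NULL
  }

  out <- vector("list", nc)
  for (i in seq_len(nc)) {
    chain <- solve(i, 2L)
    if (is.null(chain)) next
    idx <- c(i, chain)
    starts <- cand$start[i]:(cand$end[i] - r)
    end <- cand$end[idx[n]]
    rows <- lapply(starts, function(s) {
      run_mat <- cbind(start = c(s, cand$start[idx[-1]]), end = cand$end[idx])
      loop_mat <- cbind(
        start = run_mat[-n, "end"],
        end = run_mat[-1L, "start"]
      )
      list(
        start = s, end = end,
        matched_sequence = substr(seq, s + 1L, end),
        runs = run_mat, loops = loop_mat
      )
    })
    out[[i]] <- rows
  }
  rows <- unlist(out, recursive = FALSE)
  if (length(rows) == 0) return(empty_hits())
  hits <- data.frame(
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = ".",
    matched_sequence = vapply(rows, `[[`, character(1), "matched_sequence"),
    stringsAsFactors = FALSE
  )
  hits$runs <- lapply(rows, `[[`, "runs")
  hits$loops <- lapply(rows, `[[`, "loops")
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Exhaustive policy: every (start, end) admitting a decomposition with runs
# of >= r G (not necessarily maximal) and loops in [loop_min, loop_max].
scan_gq_exhaustive <- function(seq, pattern) {
  r <- pattern$min_run_length
  n <- pattern$n_runs
  lmin <- pattern$loop_min
  lmax <- pattern$loop_max
  cv <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(cv)
  # gcount[i]: consecutive G at 1-based position i (looking right).
  gcount <- integer(L + 1L)
  for (i in L:1L) gcount[i] <- if (cv[i] == "G") gcount[i + 1L] + 1L else 0L

  memo <- new.env(parent = emptyenv())
  # Reachable exclusive 0-based ends for runs k..n starting at 1-based pos.
  ends_from <- function(pos, k) {
    key <- paste0(pos, ":", k)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- integer(0)
    gmax <- if (pos <= L) gcount[pos] else 0L
    if (gmax >= r) {
      for (rl in r:gmax) {
        after <- pos + rl # 1-based position just past the run
        if (k == n) {
          res <- c(res, after - 1L) # 0-based exclusive end
        } else {
          for (l in lmin:lmax) {
            nxt <- after + l
            if (nxt > L) break
            res <- c(res, ends_from(nxt, k + 1L))
          }
        }
      }
    }
    res <- sort(unique(res))
    memo[[key]] <- res
    res
  }

  # Witness decomposition for a fixed (start, end); first found.
  witness <- function(pos, k, end1) {
    gmax <- if (pos <= L) gcount[pos] else 0L
    if (gmax < r) return(NULL)
    for (rl in r:gmax) {
      after <- pos + rl
      if (k == n) {
        if (after - 1L == end1) {
          return(list(runs = cbind(start = pos - 1L, end = after - 1L),
                      loops = NULL))
        }
      } else {
        for (l in lmin:lmax) {
          nxt <- after + l
          if (nxt > end1 + 1L) break
          sub <- witness(nxt, k + 1L, end1)
          if (!is.null(sub)) {
            return(list(
              runs = rbind(cbind(start = pos - 1L, end = after - 1L), sub$runs),
              loops = rbind(cbind(start = after - 1L, end = nxt - 1L), sub$loops)
            ))
          }
        }
      }
    }
    NULL
  }

  rows <- list()
  for (pos in seq_len(L)) {
    if (gcount[pos] < r) next
    for (e in ends_from(pos, 1L)) {
      w <- witness(pos, 1L, e)
      rows[[length(rows) + 1L]] <- list(
        start = pos - 1L, end = e,
        matched_sequence = substr(seq, pos, e),
        runs = w$runs, loops = w$loops
      )
    }
  }
  if (length(rows) == 0) return(empty_hits())
  hits <- data.frame(
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, function(x) as.integer(x$end), integer(1)),
    strand = ".",
    matched_sequence = vapply(rows, `[[`, character(1), "matched_sequence"),
    stringsAsFactors = FALSE
  )
  hits$runs <- lapply(rows, `[[`, "runs")
  hits$loops <- lapply(rows, function(x) x$loops %||% matrix(integer(0), 0, 2))
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a genome for quadruplex motifs on one or both strands
#'
#' Minus-strand scanning reverse-complements each contig, scans the literal
#' string, and maps hit coordinates back to plus-strand 0-based half-open
#' intervals with `strand == "-"`. The reported `matched_sequence` reads
#' 5' to 3' on the searched strand.
#'
#' @param genome Named character vector (or `DNAStringSet`) of contig
#'   sequences, as returned by [read_fasta()].
#' @param pattern A [gq_pattern()].
#' @param strands `"both"`, `"plus"` or `"minus"`.
#' @param policy See [scan_gq()].
#' @return Hit data frame with a `contig` column, sorted by (contig, start).
#' @export
scan_gq_genome <- function(genome, pattern = gq_pattern(),
                           strands = c("both", "plus", "minus"),
                           policy = "canonical") {
  strands <- match.arg(strands)
  genome <- as_genome(genome)
  res <- list()
  for (ctg in names(genome)) {
    seq <- genome[[ctg]]
    L <- nchar(seq)
    if (strands %in% c("both", "plus")) {
      h <- scan_gq(seq, pattern, strand_label = "+", policy = policy)
      if (nrow(h) > 0) {
        h <- cbind(data.frame(contig = ctg, stringsAsFactors = FALSE), h)
        res[[length(res) + 1L]] <- h
      }
    }
    if (strands %in% c("both", "minus")) {
      h <- scan_gq(revcomp(seq), pattern, strand_label = "-", policy = policy)
      if (nrow(h) > 0) {
        h <- mirror_hits(h, L)
        h <- cbind(data.frame(contig = ctg, stringsAsFactors = FALSE), h)
        res[[length(res) + 1L]] <- h
      }
    }
  }
  if (length(res) == 0) return(empty_hits(contig_col = TRUE))
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$contig, hits$start, hits$end, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Map hits found on the reverse complement of a length-L sequence back to
# plus-strand coordinates. Run/loop sub-intervals are mapped and re-ordered
# so that they still tile the interval left to right in plus coordinates.
mirror_hits <- function(hits, L) {
  mirror_mat <- function(m) {
    out <- cbind(start = L - m[, "end"], end = L - m[, "start"])
    out[rev(seq_len(nrow(out))), , drop = FALSE]
  }
  new_start <- L - hits$end
  new_end <- L - hits$start
  hits$start <- new_start
  hits$end <- new_end
  hits$runs <- lapply(hits$runs, mirror_mat)
  hits$loops <- lapply(hits$loops, mirror_mat)
  hits
}

#' Scan for Z-forming alternating purine/pyrimidine tracts
#'
#' Finds maximal tracts in which purines (`A`/`G`) and pyrimidines (`C`/`T`)
#' strictly alternate at every adjacent pair, the hallmark of Z-DNA/Z-RNA
#' forming flipons. `N` breaks a tract.
#'
#' @param seq Normalized nucleotide string.
#' @param min_dinucleotides Minimum number of dinucleotide units (>= 2); a
#'   tract is reported when its length is at least `2 * min_dinucleotides`.
#' @return Data frame with `start`, `end` (0-based half-open) and
#'   `dinucleotide_count`.
#' @examples
#' scan_z_tract("GCGCGCGCGC", min_dinucleotides = 5)
#' @export
scan_z_tract <- function(seq, min_dinucleotides = 3L) {
  assert_normalized_seq(seq)
  min_dinucleotides <- as.integer(min_dinucleotides)
  if (is.na(min_dinucleotides) || min_dinucleotides < 2L) {
    config_error("min_dinucleotides must be an integer >= 2")
  }
  cv <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(cv)
  empty <- data.frame(start = integer(0), end = integer(0),
                      dinucleotide_count = integer(0))
  if (L < 2L) return(empty)
  cls <- ifelse(cv %in% c("A", "G"), "R", ifelse(cv %in% c("C", "T"), "Y", NA))
  brk <- is.na(cls[-L]) | is.na(cls[-1L]) | cls[-L] == cls[-1L]
  grp <- cumsum(c(0L, brk))
  seg <- split(seq_len(L), grp)
  rows <- lapply(seg, function(ix) {
    if (length(ix) < 2L * min_dinucleotides) return(NULL)
    if (anyNA(cls[ix])) return(NULL)
    data.frame(start = ix[1] - 1L, end = ix[length(ix)],
               dinucleotide_count = length(ix) %/% 2L)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quadruplex motifs completed by an A-to-G substitution
#'
#' For each edit offset independently, substitutes the adenosine by guanosine
#' (the base inosine pairs like), rescans, and reports quadruplex hits that
#' cover the offset and are absent from the unedited scan. This models the
#' completion of a G-tetrad by A-to-I editing.
#'
#' @param seq Normalized nucleotide string.
#' @param edit_offsets Integer vector of 0-based offsets; the base at each
#'   offset must be `A`. A non-A offset yields a per-offset validation
#'   message; other offsets are still processed.
#' @param pattern A [gq_pattern()].
#' @param policy See [scan_gq()].
#' @return A list with one element per offset: `edit_offset`, `ok` (FALSE for
#'   invalid offsets, with `message`), and `new_hits` (hit data frame as in
#'   [scan_gq()]).
#' @export
edit_enabled_gq <- function(seq, edit_offsets, pattern = gq_pattern(),
                            policy = "canonical") {
  assert_pattern(pattern)
  assert_normalized_seq(seq)
  L <- nchar(seq)
  before <- scan_gq(seq, pattern, policy = policy)
  before_keys <- paste(before$start, before$end, sep = ":")
  lapply(as.integer(edit_offsets), function(o) {
    if (is.na(o) || o < 0L || o >= L) {
      return(list(edit_offset = o, ok = FALSE,
                  message = sprintf("offset %s outside sequence", o),
                  new_hits = empty_hits()))
    }
    base <- substr(seq, o + 1L, o + 1L)
    if (base != "A") {
      return(list(edit_offset = o, ok = FALSE,
                  message = sprintf("base at offset %d is '%s', expected 'A'",
                                    o, base),
                  new_hits = empty_hits()))
    }
    edited <- seq
    substr(edited, o + 1L, o + 1L) <- "G"
    after <- scan_gq(edited, pattern, policy = policy)
    keep <- after$start <= o & after$end > o &
      !(paste(after$start, after$end, sep = ":") %in% before_keys)
    list(edit_offset = o, ok = TRUE, message = NULL,
         new_hits = after[keep, , drop = FALSE])
  })
}
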
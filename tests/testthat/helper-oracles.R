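# Independent oracles used across tests. These re-derive expected results
# directly from the definitions (recursive grammar application, all-pairs
# interval comparison), not from the package's scanning machinery.

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Brute-force enumeration of canonical-policy matches by direct recursion on
# the grammar: a match is runs of >= r consecutive G (maximal within the
# match) separated by loops of length in [lmin, lmax]; one hit per match
# start (shortest-loop, earliest-run chain, final run taken fully).
# Returns a data frame of (start, end), 0-based half-open.
oracle_scan_gq <- function(seq, r = 2L, n = 4L, lmin = 1L, lmax = 10L) {
  cv <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(cv)
  gext <- integer(L + 1L) # consecutive G at position i, looking right
  for (i in rev(seq_len(L))) {
    gext[i] <- if (cv[i] == "G") gext[i + 1L] + 1L else 0L
  }
  memo <- matrix(NA_integer_, nrow = L + 1L, ncol = n)
  rec <- function(pos, k) { # canonical 0-based exclusive end, or -1
    if (pos > L) return(-1L)
    if (!is.na(memo[pos, k])) return(memo[pos, k])
    res <- -1L
    m <- gext[pos]
    if (m >= r) {
      runend <- pos + m # 1-based position just past the (maximal) run
      if (k == n) {
        res <- runend - 1L
      } else {
        for (l in max(lmin, 1L):lmax) {
          nxt <- runend + l
          if (nxt > L) break
          if (cv[nxt] != "G") next          # next run must start here
          if (cv[nxt - 1L] == "G") next     # and be maximal to the left
          sub <- rec(nxt, k + 1L)
          if (sub >= 0L) {
            res <- sub
            break
          }
        }
      }
    }
    memo[pos, k] <<- res
    res
  }
  out <- list()
  for (i in seq_len(L)) {
    if (gext[i] < r) next # a match start needs >= r G remaining in its run
    e <- rec(i, 1L)
    if (e >= 0L) out[[length(out) + 1L]] <- c(i - 1L, e)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# Quadratic all-pairs interval overlap oracle.
oracle_overlaps <- function(exons, repeats) {
  rows <- list()
  for (i in seq_len(nrow(exons))) {
    for (j in seq_len(nrow(repeats))) {
      if (exons$contig[i] != repeats$contig[j]) next
      ov <- min(exons$end[i], repeats$end[j]) -
        max(exons$start[i], repeats$start[j])
      if (ov >= 1L) {
        rows[[length(rows) + 1L]] <- data.frame(exon_idx = i, repeat_idx = j,
                                                overlap_bp = ov)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(exon_idx = integer(0), repeat_idx = integer(0),
                      overlap_bp = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$exon_idx, out$repeat_idx), , drop = FALSE]
}

# Re-check a hit's decomposition against the grammar definition.
check_witness <- function(seq, hit_row, pattern) {
  runs <- hit_row$runs[[1]]
  loops <- hit_row$loops[[1]]
  n <- pattern$n_runs
  if (nrow(runs) != n || nrow(loops) != n - 1L) return("wrong piece count")
  # runs alternate with loops and tile [start, end) exactly
  prev_end <- hit_row$start
  ivs <- list()
  for (i in seq_len(n - 1L)) {
    ivs <- c(ivs, list(runs[i, ]), list(loops[i, ]))
  }
  ivs <- c(ivs, list(runs[n, ]))
  for (iv in ivs) {
    if (iv[1] != prev_end) return("pieces do not tile")
    prev_end <- iv[2]
  }
  if (prev_end != hit_row$end) return("pieces do not reach end")
  for (i in seq_len(n)) {
    s <- substr(seq, runs[i, 1] + 1L, runs[i, 2])
    if (grepl("[^G]", s)) return("run not all G")
    if (runs[i, 2] - runs[i, 1] < pattern$min_run_length) return("run too short")
    # maximality within the match
    if (runs[i, 1] > hit_row$start &&
        substr(seq, runs[i, 1], runs[i, 1]) == "G") return("run not maximal left")
    if (runs[i, 2] < hit_row$end &&
        substr(seq, runs[i, 2] + 1L, runs[i, 2] + 1L) == "G") {
      return("run not maximal right")
    }
  }
  for (i in seq_len(n - 1L)) {
    w <- loops[i, 2] - loops[i, 1]
    if (w < pattern$loop_min || w > pattern$loop_max) return("loop length out of bounds")
  }
  TRUE
}

interval_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$start, df$end, sep = ":"))
}
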
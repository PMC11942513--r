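# Fixture builders shared across tests.

# Deterministic background that cannot match the quadruplex grammar on
# either strand (no GG, no CC), without touching the caller's RNG stream.
random_seq_fixed <- function(n, seed, gc = 0.5) {
  s <- withr::with_seed(seed, random_seq(n, gc))
  s <- gsub("GG", "GA", s, fixed = TRUE)
  gsub("CC", "CA", s, fixed = TRUE)
}

# Plant `content` at 0-based offset pos0, forcing the flanking bases to T so
# the planted runs stay maximal on both strands.
plant_at <- function(seq, pos0, content) {
  if (pos0 > 0) substr(seq, pos0, pos0) <- "T"
  substr(seq, pos0 + 1L, pos0 + nchar(content)) <- content
  after <- pos0 + nchar(content) + 1L
  if (after <= nchar(seq)) substr(seq, after, after) <- "T"
  seq
}

# Reverse-complement a synthetic dataset: mirror the genome and remap every
# coordinate and strand accordingly.
mirror_dataset <- function(sim) {
  lens <- nchar(sim$genome)
  genome <- vapply(sim$genome, revcomp, character(1))
  names(genome) <- names(sim$genome)
  flip <- function(s) ifelse(s == "+", "-", ifelse(s == "-", "+", s))
  tr <- sim$transcripts
  L <- lens[tr$contig]
  new_start <- L - tr$end
  tr$end <- L - tr$start
  tr$start <- new_start
  tr$strand <- flip(tr$strand)
  tr <- tr[order(tr$transcript_id, tr$start), ]
  rownames(tr) <- NULL
  rp <- sim$repeats
  if (nrow(rp) > 0) {
    L <- lens[rp$contig]
    new_start <- L - rp$end
    rp$end <- L - rp$start
    rp$start <- new_start
    rp$strand <- flip(rp$strand)
  }
  ed <- sim$edits
  ed$position <- lens[ed$contig] - 1L - ed$position
  ed$strand <- flip(ed$strand)
  list(genome = genome, transcripts = tr, repeats = rp, edits = ed,
       truth = sim$truth)
}
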
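# Internal helpers shared across modules.
#
# Coordinate convention: every interval held in memory is 0-based half-open
# [start, end) on the plus strand of its contig. Formats that use other
# conventions (GTF, RepeatMasker .out, 1-based edit tables) are converted at
# the read/write boundary and nowhere else.

`%||%` <- function(a, b) if (is.null(a)) b else a

qe_error <- function(msg, class) {
  stop(structure(
    class = c(class, "quadedit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

format_error  <- function(msg) qe_error(msg, "quadedit_format_error")
config_error  <- function(msg) qe_error(msg, "quadedit_config_error")
validation_error <- function(msg) qe_error(msg, "quadedit_validation_error")
lookup_error  <- function(msg) qe_error(msg, "quadedit_lookup_error")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors; `N` is preserved.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Length of a contig in a genome object (named character vector of sequences).
contig_length <- function(genome, contig) {
  if (!contig %in% names(genome)) {
    lookup_error(sprintf("contig '%s' not present in genome", contig))
  }
  nchar(genome[[contig]])
}

# Fetch one contig sequence as a plain string.
contig_seq <- function(genome, contig) {
  if (!contig %in% names(genome)) {
    lookup_error(sprintf("contig '%s' not present in genome", contig))
  }
  genome[[contig]]
}

opposite_strand <- function(strand) {
  out <- strand
  out[strand == "+"] <- "-"
  out[strand == "-"] <- "+"
  out
}

# Empty hit table with the columns scan_gq() produces.
empty_hits <- function(contig_col = FALSE) {
  df <- data.frame(
    start = integer(0), end = integer(0), strand = character(0),
    matched_sequence = character(0), stringsAsFactors = FALSE
  )
  df$runs <- list()
  df$loops <- list()
  if (contig_col) df <- cbind(data.frame(contig = character(0)), df)
  df
}
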
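#' G-quadruplex motif grammar
#'
#' Defines the quadruplex pattern as a small grammar: `n_runs` runs of at
#' least `min_run_length` consecutive guanosines, separated by loops whose
#' lengths lie in `[loop_min, loop_max]`. The default corresponds to the
#' two-tetrad minimum sufficient for an RNA quadruplex: four G-runs of two or
#' more G, loops of 1-10 arbitrary nucleotides.
#'
#' @param min_run_length Minimum guanosines per run (>= 2).
#' @param n_runs Number of G-runs (>= 2); a quadruplex needs 4.
#' @param loop_min,loop_max Loop length bounds in nucleotides,
#'   `0 <= loop_min <= loop_max`.
#' @return An object of class `gq_pattern`.
#' @examples
#' gq_pattern()                  # rGQ default: 2+ G per run
#' gq_pattern(min_run_length = 3) # stricter dGQ-style minimum
#' @export
gq_pattern <- function(min_run_length = 2L, n_runs = 4L,
                       loop_min = 1L, loop_max = 10L) {
  p <- list(
    min_run_length = as.integer(min_run_length),
    n_runs = as.integer(n_runs),
    loop_min = as.integer(loop_min),
    loop_max = as.integer(loop_max)
  )
  if (anyNA(unlist(p))) config_error("gq_pattern fields must be integers")
  if (p$min_run_length < 2L) config_error("min_run_length must be >= 2")
  if (p$n_runs < 2L) config_error("n_runs must be >= 2")
  if (p$loop_min < 0L) config_error("loop_min must be >= 0")
  if (p$loop_max < p$loop_min) config_error("loop_max must be >= loop_min")
  structure(p, class = "gq_pattern")
}

#' Named quadruplex pattern presets
#'
#' `"rgq"` (the default grammar) uses a two-G run minimum, reflecting that
#' two stacked tetrads suffice to fold an RNA quadruplex; `"dgq_strict"`
#' raises the run minimum to three, the usual requirement for a stable DNA
#' quadruplex.
#'
#' @param name One of `"rgq"`, `"dgq_strict"`.
#' @return A `gq_pattern`.
#' @export
gq_preset <- function(name = c("rgq", "dgq_strict")) {
  name <- match.arg(name)
  switch(name,
    rgq = gq_pattern(),
    dgq_strict = gq_pattern(min_run_length = 3L)
  )
}

# Minimum length of any match under the grammar.
gq_min_match_length <- function(pattern) {
  pattern$n_runs * pattern$min_run_length +
    (pattern$n_runs - 1L) * max(pattern$loop_min, 1L)
}

#' @export
print.gq_pattern <- function(x, ...) {
  cat(sprintf(
    "<gq_pattern> %d runs of G{%d,}, loops %d-%d nt (min match %d nt)\n",
    x$n_runs, x$min_run_length, x$loop_min, x$loop_max,
    gq_min_match_length(x)
  ))
  invisible(x)
}

assert_pattern <- function(pattern) {
  if (!inherits(pattern, "gq_pattern")) {
    config_error("'pattern' must be created with gq_pattern()")
  }
  pattern
}
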
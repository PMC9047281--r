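#' Generate a synthetic TE consensus library
#'
#' Produces deterministic, independent random consensi standing in for a
#' curated TE library (Dfam/RepBase style) in tests and demonstrations.
#' Family lengths are log-spaced across `length_range`, mimicking the
#' spread from short SINEs (~300 bp) to very long DNA transposons
#' (~18.5 kb); GC contents are spaced across `gc_range`. Independent
#' random sequences have distinct k-mer profiles, so any two families
#' share no local alignment above the audit module's default thresholds.
#'
#' @param n_families number of families (>= 1).
#' @param length_range two increasing lengths in bases (min >= 50).
#' @param gc_range two GC fractions in \[0, 1\].
#' @param seed master seed; every family draws from its own derived
#'   stream.
#' @return named character vector of consensi (`synthfam01`, ...).
#' @export
#' @examples
#' lib <- make_fixture_library(3, length_range = c(300, 2000), seed = 1)
#' nchar(lib)
make_fixture_library <- function(n_families = 20,
                                 length_range = c(311, 18500),
                                 gc_range = c(0.38, 0.52),
                                 seed = 1L) {
  if (n_families < 1) {
    abort("`n_families` must be >= 1.", class = "tebench_input_error")
  }
  if (length(length_range) != 2 || length_range[1] < 50 ||
      length_range[2] < length_range[1]) {
    abort("`length_range` must be two increasing lengths with min >= 50.",
          class = "tebench_input_error")
  }
  if (length(gc_range) != 2 || any(gc_range < 0 | gc_range > 1) ||
      gc_range[2] < gc_range[1]) {
    abort("`gc_range` must be two ordered fractions in [0, 1].",
          class = "tebench_input_error")
  }
  lens <- round(exp(seq(log(length_range[1]), log(length_range[2]),
                        length.out = n_families)))
  gcs <- seq(gc_range[1], gc_range[2], length.out = n_families)
  ids <- sprintf("synthfam%02d", seq_len(n_families))
  seqs <- vapply(seq_len(n_families), function(i) {
    generate_base_sequence(lens[i], gcs[i],
                           seed = derive_seed(seed, paste0("fixture/", ids[i])))
  }, character(1))
  setNames(seqs, ids)
}
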
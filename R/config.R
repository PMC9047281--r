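#' Describe one TE family to simulate
#'
#' A family specification couples a consensus sequence with the insertion
#' parameters for its copies: how many to plant, how diverged they may be,
#' which share is 5'-truncated and by how much, and which share is nested
#' inside copies of other families.
#'
#' @param family_id family name; used in the ground-truth annotation.
#' @param consensus consensus nucleotide sequence (A/C/G/T/N, case kept).
#' @param copies number of copies to insert (>= 1).
#' @param target_divergence per-copy divergence ceiling as a fraction in
#'   \[0, 1\]; every realized copy stays at or below it.
#' @param fragment_fraction fraction of copies that are 5'-truncated.
#' @param max_truncation upper bound of the truncated share of the copy
#'   length; the removed share is drawn uniformly from (0, max_truncation].
#' @param nesting_fraction fraction of copies inserted inside previously
#'   placed copies of a different family instead of into the base sequence.
#' @return a one-row tibble; rows from several calls can be combined with
#'   [dplyr::bind_rows()] to form the `families` table of a
#'   [simulation_config()].
#' @export
#' @examples
#' family_spec("AluY_like", strrep("ACGT", 80), copies = 10,
#'             target_divergence = 0.13)
family_spec <- function(family_id,
                        consensus,
                        copies,
                        target_divergence = 0.1,
                        fragment_fraction = 0,
                        max_truncation = 0.3,
                        nesting_fraction = 0) {
  spec <- tibble(
    family_id = as.character(family_id),
    consensus = as.character(consensus),
    copies = as.integer(copies),
    target_divergence = as.numeric(target_divergence),
    fragment_fraction = as.numeric(fragment_fraction),
    max_truncation = as.numeric(max_truncation),
    nesting_fraction = as.numeric(nesting_fraction)
  )
  validate_families(spec)
  spec
}

validate_families <- function(families) {
  if (!is.data.frame(families) || nrow(families) == 0) {
    abort("`families` must be a non-empty data frame of family specifications.",
          class = "tebench_input_error")
  }
  need <- c("family_id", "consensus", "copies", "target_divergence",
            "fragment_fraction", "max_truncation", "nesting_fraction")
  missing_cols <- setdiff(need, names(families))
  if (length(missing_cols)) {
    abort(paste0("`families` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tebench_input_error")
  }
  if (anyDuplicated(families$family_id)) {
    abort("duplicate family_id in `families`.", class = "tebench_input_error")
  }
  bad_seq <- grepl("[^ACGTNacgtn]", families$consensus) |
    !nzchar(families$consensus)
  if (any(bad_seq)) {
    abort(paste0("consensus of family ",
                 paste(families$family_id[bad_seq], collapse = ", "),
                 " is empty or contains symbols outside {A,C,G,T,N}."),
          class = "tebench_input_error")
  }
  if (any(families$copies < 1)) {
    abort("every family needs `copies` >= 1.", class = "tebench_input_error")
  }
  fracs <- c("target_divergence", "fragment_fraction", "max_truncation",
             "nesting_fraction")
  for (f in fracs) {
    v <- families[[f]]
    if (any(!is.finite(v) | v < 0 | v > 1)) {
      abort(paste0("`", f, "` must lie in [0, 1] for every family."),
            class = "tebench_input_error")
    }
  }
  invisible(families)
}

#' Assemble a full simulation configuration
#'
#' The configuration is the complete recipe for one simulated genome:
#' base-sequence length and GC content, the master RNG seed, the per-family
#' insertion parameters, and the mutation model shared by all families.
#'
#' The mutation model distributes the per-copy mutation budget over
#' substitutions, insertions and deletions according to
#' `mutation_weights`, with indel lengths drawn from a geometric
#' distribution with mean `indel_mean_length` bases.
#'
#' @param families tibble of family specifications; see [family_spec()].
#' @param base_length length of the random base sequence in bases.
#' @param gc_content GC fraction of the base sequence in \[0, 1\].
#' @param seed master RNG seed; all stage streams derive from it.
#' @param mutation_weights three non-negative weights
#'   (substitution, insertion, deletion); normalised to sum to 1.
#' @param indel_mean_length mean indel length in bases (>= 1).
#' @param seqid sequence name used in FASTA/GFF output.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(families,
                              base_length,
                              gc_content = 0.42,
                              seed = 1L,
                              mutation_weights = c(0.8, 0.1, 0.1),
                              indel_mean_length = 3,
                              seqid = "sim") {
  if (!is.numeric(base_length) || length(base_length) != 1 || base_length < 1) {
    abort("`base_length` must be a positive number.",
          class = "tebench_input_error")
  }
  if (!is.numeric(gc_content) || gc_content < 0 || gc_content > 1) {
    abort("`gc_content` must lie in [0, 1].", class = "tebench_input_error")
  }
  if (length(mutation_weights) != 3 || any(mutation_weights < 0) ||
      sum(mutation_weights) <= 0) {
    abort("`mutation_weights` must be three non-negative weights.",
          class = "tebench_input_error")
  }
  if (indel_mean_length < 1) {
    abort("`indel_mean_length` must be >= 1 base.",
          class = "tebench_input_error")
  }
  validate_families(families)
  structure(
    list(
      base_length = as.integer(base_length),
      gc_content = as.numeric(gc_content),
      seed = as.integer(seed),
      families = as_tibble(families),
      mutation_weights = mutation_weights / sum(mutation_weights),
      indel_mean_length = as.numeric(indel_mean_length),
      seqid = as.character(seqid)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  base:", format(x$base_length, big.mark = ","), "bp at GC",
      sprintf("%.1f%%", 100 * x$gc_content), " seed", x$seed, "\n")
  cat("  families:", nrow(x$families), " total copies:",
      sum(x$families$copies), "\n")
  cat("  mutation weights (sub/ins/del):",
      paste(sprintf("%.2f", x$mutation_weights), collapse = "/"),
      " indel mean:", x$indel_mean_length, "bp\n")
  invisible(x)
}

#' Configuration emulating the benchmark's simulated dataset
#'
#' Builds a ready-to-run configuration that mirrors the composition of the
#' simulated benchmark genome: a base sequence at human-like 42% GC plus an
#' equal-to-1.5x mass of TE copies from 20 synthetic families, so that TEs
#' make up 60% of the emitted genome. At `scale = 1` this is a 40 Mb base
#' carrying 60 Mb of TE sequence; the default `scale = 0.1` keeps the same
#' composition at a tenth of the size.
#'
#' Family consensi come from [make_fixture_library()] with lengths
#' log-spaced between 311 bp (SINE-like) and 18.5 kb (Polinton-like).
#' Per-family copy counts are chosen so each family contributes an equal
#' share of the TE mass after truncation. Divergence targets range from 5%
#' to the 30% cap, with most families in the 5-10% band so the bulk of
#' copies stays 90-95% identical to their consensus.
#'
#' @param scale linear scale factor on both base and TE mass.
#' @param seed master RNG seed.
#' @param n_families number of synthetic families.
#' @param te_fraction TE share of the final genome (default 0.6).
#' @return a `sim_config`.
#' @export
simulated_dataset_config <- function(scale = 0.1, seed = 1L,
                                     n_families = 20, te_fraction = 0.6) {
  stopifnot(scale > 0, te_fraction > 0, te_fraction < 1, n_families >= 1)
  base_length <- round(40e6 * scale)
  te_total <- base_length * te_fraction / (1 - te_fraction)
  lib <- make_fixture_library(n_families = n_families,
                              length_range = c(311, 18500),
                              seed = derive_seed(seed, "fixture-library"))
  fragment_fraction <- 0.1
  max_truncation <- 0.3
  nesting_fraction <- 0.05
  # most families lightly diverged (5-10%), a tail reaching the 30% cap
  n_low <- ceiling(n_families * 0.6)
  targets <- c(seq(0.05, 0.10, length.out = n_low),
               seq(0.12, 0.30, length.out = n_families - n_low))
  lens <- nchar(lib)
  exp_len <- lens * (1 - fragment_fraction * max_truncation / 2)
  budget <- te_total / n_families
  copies <- pmax(1L, as.integer(round(budget / exp_len)))
  families <- tibble(
    family_id = names(lib),
    consensus = unname(lib),
    copies = copies,
    target_divergence = targets[seq_len(n_families)],
    fragment_fraction = fragment_fraction,
    max_truncation = max_truncation,
    nesting_fraction = nesting_fraction
  )
  simulation_config(families, base_length = base_length, gc_content = 0.42,
                    seed = seed)
}
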
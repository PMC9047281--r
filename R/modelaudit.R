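#' Align de novo consensus models against reference families
#'
#' Maps every model onto every reference family with local
#' (Smith-Waterman) alignment in both orientations. Alignment is
#' iterative: after each hit the matched model span is masked and the pair
#' is realigned, so a model containing two copies of a family (a
#' homodimer) yields two hits. Hits shorter than `min_hit_length` or below
#' `min_identity` are discarded.
#'
#' Precomputed hits from an external aligner (e.g. tabular BLAST output
#' read with [read_blast_hits()]) can be used instead wherever a hit table
#' is accepted; the schema is identical.
#'
#' @param models named character vector of model sequences.
#' @param references named character vector of family consensus sequences.
#' @param min_identity minimum percent identity of a hit (default 60).
#' @param min_hit_length minimum aligned length in bases (default 50).
#' @param max_hits_per_pair cap on iterative hits per model/family pair.
#' @return tibble of hits: `model_id`, `family_id`, `identity` (percent),
#'   `model_start`, `model_end` (on the original model), `ref_start`,
#'   `ref_end`, `orientation` (+/-), `score`.
#' @export
align_models <- function(models, references, min_identity = 60,
                         min_hit_length = 50, max_hits_per_pair = 8) {
  check_seq_set <- function(x, what) {
    if (length(x) == 0 || is.null(names(x)) || any(!nzchar(names(x)))) {
      abort(paste0("`", what, "` must be a non-empty named sequence set."),
            class = "tebench_input_error")
    }
    if (anyDuplicated(names(x))) {
      abort(paste0("duplicate sequence identifiers in `", what, "`."),
            class = "tebench_input_error")
    }
  }
  check_seq_set(models, "models")
  check_seq_set(references, "references")
  mat <- alignment_matrix()
  rows <- list()
  for (m in names(models)) {
    for (r in names(references)) {
      for (ori in c("+", "-")) {
        q <- toupper(models[[m]])
        if (ori == "-") q <- revcomp(q)
        hits <- iterate_local_hits(q, toupper(references[[r]]), mat,
                                   min_identity, min_hit_length,
                                   max_hits_per_pair)
        if (nrow(hits) == 0) next
        if (ori == "-") {
          qlen <- nchar(q)
          new_start <- qlen - hits$model_end + 1L
          hits$model_end <- qlen - hits$model_start + 1L
          hits$model_start <- new_start
        }
        hits$model_id <- m
        hits$family_id <- r
        hits$orientation <- ori
        rows[[length(rows) + 1L]] <- hits
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(model_id = character(), family_id = character(),
                  identity = numeric(), model_start = integer(),
                  model_end = integer(), ref_start = integer(),
                  ref_end = integer(), orientation = character(),
                  score = numeric()))
  }
  out <- out[, c("model_id", "family_id", "identity", "model_start",
                 "model_end", "ref_start", "ref_end", "orientation",
                 "score")]
  arrange(out, .data$model_id, .data$family_id, dplyr::desc(.data$score))
}

# ACGTN scoring: blast-like match/mismatch, N heavily penalised so that
# masked model spans cannot re-align.
alignment_matrix <- function(match = 2, mismatch = -3, n_penalty = -6) {
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(mat) <- match
  mat["N", ] <- n_penalty
  mat[, "N"] <- n_penalty
  mat
}

iterate_local_hits <- function(query, subject, mat, min_identity,
                               min_hit_length, max_hits) {
  out <- list()
  q <- query
  for (k in seq_len(max_hits)) {
    aln <- Biostrings::pairwiseAlignment(q, subject, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    if (Biostrings::score(aln) <= 0) break
    prng <- aln@pattern@range
    srng <- aln@subject@range
    alen <- Biostrings::nchar(aln)
    ident <- Biostrings::pid(aln)
    if (IRanges::width(prng) < min_hit_length || ident < min_identity) break
    out[[k]] <- tibble(identity = ident,
                       model_start = IRanges::start(prng),
                       model_end = IRanges::end(prng),
                       ref_start = IRanges::start(srng),
                       ref_end = IRanges::end(srng),
                       score = Biostrings::score(aln))
    substr(q, IRanges::start(prng), IRanges::end(prng)) <-
      strrep("N", IRanges::width(prng))
  }
  bind_rows(out)
}

#' Classify de novo models against reference families
#'
#' Assigns each model an accuracy category from its hits:
#' \describe{
#'   \item{perfect}{all hits to a single family, forming one collinear
#'     chain with >= `perfect_identity` identity and >=
#'     `perfect_coverage` percent of the reference covered;}
#'   \item{good}{>= `perfect_identity` identity with `good_coverage` to
#'     `perfect_coverage` percent reference coverage;}
#'   \item{present}{any qualifying hit below that;}
#'   \item{not_found}{no qualifying hit.}
#' }
#' Pathology flags: `homodimer` when two essentially non-overlapping model
#' spans map onto overlapping reference spans of one family (a duplicated
#' consensus); `chimera` when one model has qualifying hits to two or more
#' families (fused fragments, typically from nested insertions);
#' `fragment` when the best reference coverage stays below
#' `good_coverage`; `redundant` when several models share the same best
#' family.
#'
#' @param hits hit table from [align_models()] (or external hits with the
#'   same schema).
#' @param references named character vector of reference sequences (for
#'   coverage denominators).
#' @param models optional named character vector of model sequences; when
#'   given, models without hits are reported as `not_found`.
#' @param perfect_identity identity threshold in percent (default 95).
#' @param perfect_coverage reference-coverage threshold for `perfect`.
#' @param good_coverage reference-coverage threshold for `good`.
#' @param chain_overlap_tol tolerated overlap between chained hits as a
#'   fraction of the shorter hit (default 0.1).
#' @return tibble of verdicts: `model_id`, `category`, `best_family`,
#'   `best_identity`, `best_coverage` (percent of that family's
#'   reference), `flags` (comma-separated), `n_families`.
#' @export
classify_models <- function(hits, references, models = NULL,
                            perfect_identity = 95, perfect_coverage = 95,
                            good_coverage = 50, chain_overlap_tol = 0.1) {
  ref_len <- setNames(nchar(references), names(references))
  ids <- if (!is.null(models)) names(models) else unique(hits$model_id)
  verdicts <- purrr::map_dfr(ids, function(m) {
    h <- hits[hits$model_id == m, , drop = FALSE]
    if (nrow(h) == 0) {
      return(tibble(model_id = m, category = "not_found",
                    best_family = NA_character_, best_identity = NA_real_,
                    best_coverage = NA_real_, flags = "",
                    n_families = 0L))
    }
    per_fam <- h |>
      group_by(.data$family_id) |>
      summarise(
        coverage = 100 * sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(.data$ref_start, .data$ref_end)))) /
          ref_len[[.data$family_id[1]]],
        identity = sum(.data$identity *
                         (.data$ref_end - .data$ref_start + 1)) /
          sum(.data$ref_end - .data$ref_start + 1),
        .groups = "drop") |>
      arrange(dplyr::desc(.data$coverage * .data$identity))
    best <- per_fam[1, ]
    bh <- h[h$family_id == best$family_id, , drop = FALSE]
    single_chain <- is_collinear_chain(bh, chain_overlap_tol)
    category <- if (nrow(per_fam) == 1 && single_chain &&
                    best$identity >= perfect_identity &&
                    best$coverage >= perfect_coverage) {
      "perfect"
    } else if (best$identity >= perfect_identity &&
               best$coverage >= good_coverage) {
      "good"
    } else {
      "present"
    }
    flags <- character(0)
    if (nrow(per_fam) >= 2) flags <- c(flags, "chimera")
    if (has_homodimer(bh)) flags <- c(flags, "homodimer")
    if (best$coverage < good_coverage) flags <- c(flags, "fragment")
    tibble(model_id = m, category = category,
           best_family = best$family_id, best_identity = best$identity,
           best_coverage = best$coverage,
           flags = paste(flags, collapse = ","),
           n_families = nrow(per_fam))
  })
  dup_fams <- verdicts |>
    filter(!is.na(.data$best_family)) |>
    dplyr::count(.data$best_family) |>
    filter(.data$n > 1) |>
    pull(.data$best_family)
  verdicts$flags <- ifelse(
    verdicts$best_family %in% dup_fams,
    ifelse(nzchar(verdicts$flags),
           paste0(verdicts$flags, ",redundant"), "redundant"),
    verdicts$flags)
  verdicts
}

# hits (one model, one family) form a single collinear chain when, walked
# in reference order, model spans advance in the same direction with at
# most `tol` fractional overlap on the reference.
is_collinear_chain <- function(h, tol) {
  if (nrow(h) <= 1) return(TRUE)
  if (length(unique(h$orientation)) > 1) return(FALSE)
  h <- h[order(h$ref_start, h$ref_end), , drop = FALSE]
  ref_ok <- TRUE
  for (i in seq_len(nrow(h) - 1)) {
    ov <- h$ref_end[i] - h$ref_start[i + 1] + 1
    shorter <- min(h$ref_end[i] - h$ref_start[i] + 1,
                   h$ref_end[i + 1] - h$ref_start[i + 1] + 1)
    if (ov > tol * shorter) ref_ok <- FALSE
  }
  model_order <- if (h$orientation[1] == "+") h$model_start else
    rev(h$model_start)
  ref_ok && !is.unsorted(model_order)
}

# two essentially disjoint model spans mapping onto substantially
# overlapping reference spans: a duplicated (dimeric) consensus
has_homodimer <- function(h, model_tol = 0.1, ref_min_overlap = 0.5) {
  n <- nrow(h)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m_ov <- min(h$model_end[i], h$model_end[j]) -
        max(h$model_start[i], h$model_start[j]) + 1
      m_short <- min(h$model_end[i] - h$model_start[i] + 1,
                     h$model_end[j] - h$model_start[j] + 1)
      r_ov <- min(h$ref_end[i], h$ref_end[j]) -
        max(h$ref_start[i], h$ref_start[j]) + 1
      r_short <- min(h$ref_end[i] - h$ref_start[i] + 1,
                     h$ref_end[j] - h$ref_start[j] + 1)
      if (m_ov <= model_tol * m_short && r_ov >= ref_min_overlap * r_short) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Per-family recovery report
#'
#' Summarises model verdicts from the reference side: how many models each
#' family gave rise to, the best coverage and category achieved, and which
#' families were missed entirely (no model maps to them).
#'
#' @param verdicts tibble from [classify_models()].
#' @param references named character vector of reference sequences.
#' @return tibble: `family_id`, `n_models`, `best_coverage`,
#'   `best_category`, `missed`. The sum of `n_models` equals the number of
#'   models with a best family; `attr(, "n_models_total")` carries the
#'   total model count including `not_found` ones.
#' @export
family_report <- function(verdicts, references) {
  cat_rank <- c(perfect = 1, good = 2, present = 3, not_found = 4)
  out <- purrr::map_dfr(names(references), function(fam) {
    v <- verdicts[!is.na(verdicts$best_family) &
                    verdicts$best_family == fam, , drop = FALSE]
    tibble(
      family_id = fam,
      n_models = nrow(v),
      best_coverage = if (nrow(v)) max(v$best_coverage) else NA_real_,
      best_category = if (nrow(v)) {
        names(which.min(cat_rank[v$category]))
      } else {
        NA_character_
      },
      missed = nrow(v) == 0
    )
  })
  attr(out, "n_models_total") <- nrow(verdicts)
  out
}

#' Tiling table of one family's models on reference coordinates
#'
#' Lays every hit of every model for one family along the reference, for
#' tiling/coverage plots of how de novo models reconstruct a family.
#'
#' @param hits hit table from [align_models()].
#' @param family family identifier to tile.
#' @return tibble sorted by `ref_start`: `model_id`, `ref_start`,
#'   `ref_end`, `identity`, `orientation`.
#' @export
model_tiling <- function(hits, family) {
  h <- hits[hits$family_id == family,
            c("model_id", "ref_start", "ref_end", "identity", "orientation")]
  arrange(h, .data$ref_start, .data$ref_end, .data$model_id)
}

#' Read precomputed alignment hits in tabular BLAST layout
#'
#' Accepts the standard 12-column tab-separated pairwise-alignment format
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, evalue, bitscore) so an external
#' aligner can replace the internal one; subject coordinates with
#' sstart > send denote minus-orientation hits.
#'
#' @param path file path.
#' @return hit tibble in the [align_models()] schema.
#' @export
read_blast_hits <- function(path) {
  cols <- c("model_id", "family_id", "identity", "length", "mismatch",
            "gapopen", "model_start", "model_end", "ref_start", "ref_end",
            "evalue", "score")
  df <- readr::read_tsv(path, col_names = cols, comment = "#",
                        show_col_types = FALSE)
  if (ncol(df) != 12) {
    abort("expected 12 tab-separated columns of tabular alignment output.",
          class = "tebench_input_error")
  }
  minus <- df$ref_start > df$ref_end
  tmp <- df$ref_start[minus]
  df$ref_start[minus] <- df$ref_end[minus]
  df$ref_end[minus] <- tmp
  df$orientation <- ifelse(minus, "-", "+")
  df[, c("model_id", "family_id", "identity", "model_start", "model_end",
         "ref_start", "ref_end", "orientation", "score")]
}
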
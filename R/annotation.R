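#' Canonicalise an annotation table
#'
#' An annotation set is an ordinary tibble of genomic intervals with
#' 1-based inclusive `start`/`end` on named sequences, plus any attribute
#' columns (`family`, `divergence`, `source`, ...). This helper validates
#' the required columns, coerces coordinates to integers and sorts by
#' (seqid, start, end).
#'
#' @param x data frame with at least `seqid`, `start`, `end`.
#' @param seq_lengths optional named vector (or two-column data frame) of
#'   sequence lengths; when given, intervals are checked to lie within.
#' @return a sorted tibble.
#' @export
as_annotation <- function(x, seq_lengths = NULL) {
  x <- as_tibble(x)
  need <- c("seqid", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("annotation is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "tebench_input_error")
  }
  x$seqid <- as.character(x$seqid)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (!"strand" %in% names(x)) x$strand <- "*"
  bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$start < 1 |
                 x$end < x$start)
  if (length(bad)) {
    abort(paste0("invalid interval(s) at row(s) ",
                 paste(head(bad, 5), collapse = ", "),
                 ": need 1 <= start <= end."),
          class = "tebench_input_error")
  }
  if (!is.null(seq_lengths)) {
    sl <- as_seq_lengths(seq_lengths)
    unknown <- setdiff(unique(x$seqid), names(sl))
    if (length(unknown)) {
      abort(paste0("interval seqid(s) absent from seq_lengths: ",
                   paste(unknown, collapse = ", ")),
            class = "tebench_input_error")
    }
    over <- which(x$end > sl[x$seqid])
    if (length(over)) {
      abort(paste0("interval(s) beyond sequence end at row(s) ",
                   paste(head(over, 5), collapse = ", "), "."),
            class = "tebench_input_error")
    }
  }
  arrange(x, .data$seqid, .data$start, .data$end)
}

as_seq_lengths <- function(seq_lengths) {
  if (is.data.frame(seq_lengths)) {
    sl <- setNames(as.numeric(seq_lengths[[2]]),
                   as.character(seq_lengths[[1]]))
  } else {
    sl <- seq_lengths
  }
  if (is.null(names(sl)) || any(!nzchar(names(sl)))) {
    abort("`seq_lengths` must be named by seqid.",
          class = "tebench_input_error")
  }
  if (any(!is.finite(sl) | sl < 1)) {
    abort("`seq_lengths` must be positive.", class = "tebench_input_error")
  }
  sl
}

# split an annotation tibble into a named list of IRanges per seqid
annotation_ranges <- function(x) {
  lapply(split(x[c("start", "end")], x$seqid), function(df) {
    IRanges::IRanges(start = df$start, end = df$end)
  })
}

ranges_to_tibble <- function(ir_by_seq) {
  rows <- purrr::imap(ir_by_seq, function(ir, sid) {
    if (length(ir) == 0) return(NULL)
    tibble(seqid = sid, start = IRanges::start(ir), end = IRanges::end(ir))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(seqid = character(), start = integer(), end = integer())
  }
  arrange(out, .data$seqid, .data$start, .data$end)
}

#' Merge overlapping, contained and adjacent intervals
#'
#' Intervals on the same sequence that overlap, lie inside one another, or
#' are immediately adjacent (or separated by at most `max_gap` bases) are
#' merged into one. Repeat detectors — k-mer counters in particular —
#' report many overlapping fragments; merging reduces an annotation to its
#' covered base set before base-level comparison. The operation is
#' idempotent and insensitive to input order. String attributes of merged
#' members are concatenated (unique values, comma-separated).
#'
#' @param x annotation tibble.
#' @param max_gap merge intervals separated by at most this many
#'   intervening bases (default 0: only overlap, containment and
#'   bookended adjacency).
#' @return merged annotation tibble with columns `seqid`, `start`, `end`,
#'   `strand` (kept when unanimous, else `*`), `n_merged`, and
#'   concatenated `family`/`source` when present in the input.
#' @export
#' @examples
#' x <- tibble::tibble(seqid = "chr", start = c(1, 5, 11), end = c(10, 20, 20))
#' merge_intervals(x)
merge_intervals <- function(x, max_gap = 0) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || max_gap < 0) {
    abort("`max_gap` must be a non-negative integer.",
          class = "tebench_input_error")
  }
  x <- as_annotation(x)
  if (nrow(x) == 0) {
    return(mutate(x, n_merged = integer()))
  }
  out <- lapply(split(x, x$seqid), function(df) {
    ir <- IRanges::IRanges(df$start, df$end)
    red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1)
    hit <- IRanges::findOverlaps(ir, red, maxgap = max_gap)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    res <- tibble(seqid = df$seqid[1],
                  start = IRanges::start(red),
                  end = IRanges::end(red),
                  n_merged = as.integer(table(factor(grp, levels = seq_along(red)))))
    res$strand <- vapply(seq_along(red), function(g) {
      s <- unique(df$strand[grp == g])
      if (length(s) == 1) s else "*"
    }, character(1))
    for (col in intersect(c("family", "source"), names(df))) {
      res[[col]] <- vapply(seq_along(red), function(g) {
        paste(unique(df[[col]][grp == g]), collapse = ",")
      }, character(1))
    }
    res
  })
  arrange(bind_rows(out), .data$seqid, .data$start, .data$end)
}

#' Subtract masked regions from an annotation
#'
#' Removes every base covered by `mask` from the intervals of `x`,
#' splitting intervals where necessary; attribute columns are carried over
#' to the resulting pieces. Typical use: excluding tandem-repeat regions
#' (e.g. a Tandem Repeats Finder annotation) before base-level scoring.
#'
#' @param x annotation tibble.
#' @param mask annotation tibble of regions to remove; empty mask returns
#'   `x` unchanged (canonicalised).
#' @return annotation tibble.
#' @export
exclude_regions <- function(x, mask) {
  x <- as_annotation(x)
  mask <- as_annotation(mask)
  if (nrow(x) == 0 || nrow(mask) == 0) return(x)
  mask_ir <- lapply(split(mask[c("start", "end")], mask$seqid), function(df) {
    IRanges::reduce(IRanges::IRanges(df$start, df$end))
  })
  pieces <- lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, , drop = FALSE]
    m <- mask_ir[[row$seqid]]
    if (is.null(m)) return(row)
    kept <- IRanges::setdiff(IRanges::IRanges(row$start, row$end), m)
    if (length(kept) == 0) return(NULL)
    out <- row[rep(1, length(kept)), , drop = FALSE]
    out$start <- IRanges::start(kept)
    out$end <- IRanges::end(kept)
    out
  })
  out <- bind_rows(pieces)
  if (nrow(out) == 0) {
    out <- x[0, , drop = FALSE]
  }
  arrange(out, .data$seqid, .data$start, .data$end)
}

covered_bases <- function(x) {
  x <- as_annotation(x)
  if (nrow(x) == 0) return(0)
  sum(vapply(annotation_ranges(x), function(ir) {
    sum(IRanges::width(IRanges::reduce(ir)))
  }, numeric(1)))
}
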
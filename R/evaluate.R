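#' Base-level confusion matrix of a predicted vs a reference annotation
#'
#' Every base of every evaluated sequence is classified by position alone
#' (strand is ignored): annotated in both sets — true positive; in the
#' prediction only — false positive; in the reference only — false
#' negative; in neither — true negative. Both sets are reduced to their
#' covered base sets first, so overlapping records never double-count.
#' Counts are summed across sequences.
#'
#' @param reference reference annotation tibble.
#' @param prediction predicted annotation tibble.
#' @param seq_lengths named vector (or two-column data frame) of the
#'   lengths of all evaluated sequences; both annotations must lie within.
#' @param mask optional annotation of regions to exclude from the
#'   comparison entirely (subtracted from both sets and from the genome
#'   length before counting).
#' @return an object of class `te_confusion` with fields `tp`, `fp`,
#'   `fn`, `tn` and `total`. Use [mcc()] or [eval_metrics()] on it;
#'   [tidy()] and [glance()] methods are provided.
#' @export
#' @examples
#' ref <- tibble::tibble(seqid = "chr", start = 1, end = 50)
#' pred <- tibble::tibble(seqid = "chr", start = 26, end = 75)
#' confusion_matrix(ref, pred, c(chr = 100))
confusion_matrix <- function(reference, prediction, seq_lengths,
                             mask = NULL) {
  sl <- as_seq_lengths(seq_lengths)
  reference <- as_annotation(reference, sl)
  prediction <- as_annotation(prediction, sl)
  total <- sum(sl)
  if (!is.null(mask)) {
    mask <- as_annotation(mask, sl)
    reference <- exclude_regions(reference, mask)
    prediction <- exclude_regions(prediction, mask)
    total <- total - covered_bases(mask)
  }
  ref_ir <- annotation_ranges(reference)
  pred_ir <- annotation_ranges(prediction)
  tp <- fp <- fn <- 0
  for (sid in union(names(ref_ir), names(pred_ir))) {
    r <- IRanges::reduce(ref_ir[[sid]] %||% IRanges::IRanges())
    p <- IRanges::reduce(pred_ir[[sid]] %||% IRanges::IRanges())
    tp <- tp + sum(IRanges::width(IRanges::intersect(r, p)))
    fp <- fp + sum(IRanges::width(IRanges::setdiff(p, r)))
    fn <- fn + sum(IRanges::width(IRanges::setdiff(r, p)))
  }
  tn <- total - tp - fp - fn
  if (tn < 0) {
    abort("annotated bases exceed the genome length; check seq_lengths.",
          class = "tebench_internal_error")
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, total = total),
            class = "te_confusion")
}

#' @export
print.te_confusion <- function(x, ...) {
  cat("<te_confusion>  TP:", x$tp, " FP:", x$fp, " FN:", x$fn,
      " TN:", x$tn, "\n")
  m <- mcc(x)
  cat(sprintf("  MCC: %.4f%s\n", m,
              if (isTRUE(attr(m, "degenerate"))) " (degenerate)" else ""))
  invisible(x)
}

#' @describeIn confusion_matrix long-format counts (class, bases).
#' @param x a `te_confusion`.
#' @param ... unused.
#' @export
tidy.te_confusion <- function(x, ...) {
  tibble(class = c("TP", "FP", "FN", "TN"),
         bases = c(x$tp, x$fp, x$fn, x$tn))
}

#' @describeIn confusion_matrix one-row summary with all derived metrics;
#'   see [eval_metrics()].
#' @export
glance.te_confusion <- function(x, ...) {
  eval_metrics(x)
}

#' Matthews correlation coefficient of a confusion matrix
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), a balanced
#' binary-classification score in \[-1, 1\]: 1 when every base is
#' classified correctly, 0 when the prediction is no better than random
#' guessing, -1 when every base is classified wrongly. When any marginal
#' sum is zero the quotient is undefined; by the continuity convention the
#' value 0 is returned, flagged via `attr(, "degenerate")`.
#'
#' @param cm a `te_confusion` (or a list with tp/fp/fn/tn counts).
#' @return a double in \[-1, 1\].
#' @export
#' @examples
#' mcc(list(tp = 50, fp = 0, fn = 0, tn = 50)) # 1
mcc <- function(cm) {
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  fn <- as.numeric(cm$fn); tn <- as.numeric(cm$tn)
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    return(structure(0, degenerate = TRUE))
  }
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Derived metrics of a base-level confusion matrix
#'
#' @param cm a `te_confusion`.
#' @return one-row tibble: base counts, `mcc`, `sensitivity` (recall),
#'   `specificity`, `precision`, `f1`, and `degenerate` (TRUE when a zero
#'   marginal made the MCC undefined; other undefined ratios are `NA`).
#' @export
eval_metrics <- function(cm) {
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  fn <- as.numeric(cm$fn); tn <- as.numeric(cm$tn)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  m <- mcc(cm)
  prec <- safe_div(tp, tp + fp)
  sens <- safe_div(tp, tp + fn)
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    mcc = as.numeric(m),
    sensitivity = sens,
    specificity = safe_div(tn, tn + fp),
    precision = prec,
    f1 = if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else
      2 * prec * sens / (prec + sens),
    degenerate = isTRUE(attr(m, "degenerate"))
  )
}

#' Detection coverage of reference TEs as a function of their identity
#'
#' Groups reference intervals into sequence-identity bins (identity =
#' 100 - divergence, percent) and reports, per bin, the fraction of
#' reference TE bases overlapped by the prediction. More diverged
#' (lower-identity) copies are harder to detect; this table quantifies
#' that decay for one tool.
#'
#' @param reference annotation tibble carrying a per-interval `identity`
#'   or `divergence` (percent) column — the simulator's ground truth
#'   provides `divergence`.
#' @param prediction predicted annotation tibble.
#' @param bins bin edges in identity percent (default `seq(60, 100, 5)`);
#'   bins are closed on the left, the top bin closed on both sides.
#' @return tibble of class `te_coverage`: `bin_lo`, `bin_hi`, `ref_bases`,
#'   `detected_bases`, `coverage`.
#' @export
coverage_by_identity <- function(reference, prediction,
                                 bins = seq(60, 100, by = 5)) {
  reference <- as_annotation(reference)
  prediction <- as_annotation(prediction)
  if (!"identity" %in% names(reference)) {
    if (!"divergence" %in% names(reference)) {
      abort("reference needs an `identity` or `divergence` (percent) column.",
            class = "tebench_input_error")
    }
    reference$identity <- 100 - reference$divergence
  }
  bad <- which(!is.finite(reference$identity))
  if (length(bad)) {
    abort(paste0("missing identity at reference row(s) ",
                 paste(head(bad, 5), collapse = ", "), "."),
          class = "tebench_input_error")
  }
  if (length(bins) < 2 || is.unsorted(bins, strictly = TRUE)) {
    abort("`bins` must be strictly increasing edges.",
          class = "tebench_input_error")
  }
  pred_ir <- lapply(annotation_ranges(prediction), IRanges::reduce)
  detected <- numeric(nrow(reference))
  for (sid in unique(reference$seqid)) {
    idx <- which(reference$seqid == sid)
    p <- pred_ir[[sid]]
    if (is.null(p) || length(p) == 0) next
    r <- IRanges::IRanges(reference$start[idx], reference$end[idx])
    hits <- IRanges::findOverlaps(r, p)
    if (length(hits) == 0) next
    ov <- IRanges::pintersect(r[S4Vectors::queryHits(hits)],
                              p[S4Vectors::subjectHits(hits)])
    w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    detected[idx[as.integer(names(w))]] <- as.numeric(w)
  }
  # closed-left bins, top bin closed on both sides
  cut_idx <- findInterval(reference$identity, bins, rightmost.closed = TRUE,
                          left.open = FALSE)
  keep <- cut_idx >= 1 & cut_idx <= length(bins) - 1
  widths <- reference$end - reference$start + 1
  df <- tibble(bin = cut_idx[keep], ref = widths[keep],
               det = detected[keep])
  agg <- df |>
    group_by(.data$bin) |>
    summarise(ref_bases = sum(.data$ref), detected_bases = sum(.data$det),
              .groups = "drop")
  out <- tibble(bin = seq_len(length(bins) - 1),
                bin_lo = bins[-length(bins)], bin_hi = bins[-1]) |>
    left_join(agg, by = "bin") |>
    mutate(ref_bases = dplyr::coalesce(.data$ref_bases, 0),
           detected_bases = dplyr::coalesce(.data$detected_bases, 0),
           coverage = ifelse(.data$ref_bases > 0,
                             .data$detected_bases / .data$ref_bases,
                             NA_real_)) |>
    select(-"bin")
  class(out) <- c("te_coverage", class(out))
  out
}

#' Repeat landscape: annotated bases per family and divergence bin
#'
#' The classic landscape histogram — for each family, how many annotated
#' bases sit at each divergence from the consensus. For simulator ground
#' truth the support of every family's histogram is bounded by that
#' family's divergence target.
#'
#' @param reference annotation tibble with `family` and `divergence`
#'   (percent) columns.
#' @param bin_width divergence bin width in percent (default 1).
#' @return tibble of class `te_landscape`: `family`, `bin_lo`, `bin_hi`,
#'   `bases`.
#' @export
divergence_landscape <- function(reference, bin_width = 1) {
  reference <- as_annotation(reference)
  for (col in c("family", "divergence")) {
    if (!col %in% names(reference)) {
      abort(paste0("reference needs a `", col, "` column."),
            class = "tebench_input_error")
    }
  }
  bad <- which(!is.finite(reference$divergence))
  if (length(bad)) {
    abort(paste0("missing divergence at reference row(s) ",
                 paste(head(bad, 5), collapse = ", "), "."),
          class = "tebench_input_error")
  }
  out <- reference |>
    mutate(bin_lo = floor(.data$divergence / bin_width) * bin_width,
           width = .data$end - .data$start + 1) |>
    group_by(.data$family, .data$bin_lo) |>
    summarise(bases = sum(.data$width), .groups = "drop") |>
    mutate(bin_hi = .data$bin_lo + bin_width) |>
    select("family", "bin_lo", "bin_hi", "bases") |>
    arrange(.data$family, .data$bin_lo)
  class(out) <- c("te_landscape", class(out))
  out
}

#' Track table for plotting predictions against a reference
#'
#' For each named prediction set, splits the requested region into
#' segments labelled TP (annotated in both), FP (prediction only) and FN
#' (reference only) — the long-format input for track plots comparing
#' tools along a genome window.
#'
#' @param reference reference annotation tibble.
#' @param predictions named list of prediction annotation tibbles.
#' @param region one-row data frame (or list) with `seqid`, `start`,
#'   `end`.
#' @param seq_lengths named sequence lengths; the region must lie within.
#' @return tibble of class `te_tracks`: `track`, `seqid`, `start`, `end`,
#'   `class`.
#' @export
track_table <- function(reference, predictions, region, seq_lengths) {
  sl <- as_seq_lengths(seq_lengths)
  if (is.null(names(predictions)) || any(!nzchar(names(predictions)))) {
    abort("`predictions` must be a named list.", class = "tebench_input_error")
  }
  region <- as.list(region)
  if (!region$seqid %in% names(sl) || region$start < 1 ||
      region$end > sl[[region$seqid]] || region$start > region$end) {
    abort("`region` must lie within the declared sequence lengths.",
          class = "tebench_input_error")
  }
  win <- IRanges::IRanges(region$start, region$end)
  ref <- as_annotation(reference, sl)
  ref_ir <- IRanges::reduce(
    annotation_ranges(ref[ref$seqid == region$seqid, ])[[region$seqid]] %||%
      IRanges::IRanges())
  rows <- purrr::imap(predictions, function(pred, nm) {
    pred <- as_annotation(pred, sl)
    p_ir <- IRanges::reduce(
      annotation_ranges(pred[pred$seqid == region$seqid, ])[[region$seqid]] %||%
        IRanges::IRanges())
    seg <- list(TP = IRanges::intersect(ref_ir, p_ir),
                FP = IRanges::setdiff(p_ir, ref_ir),
                FN = IRanges::setdiff(ref_ir, p_ir))
    purrr::imap_dfr(seg, function(ir, cls) {
      ir <- IRanges::intersect(ir, win)
      if (length(ir) == 0) return(NULL)
      tibble(track = nm, seqid = region$seqid,
             start = IRanges::start(ir), end = IRanges::end(ir),
             class = cls)
    })
  })
  out <- arrange(bind_rows(rows), .data$track, .data$start)
  if (nrow(out) == 0) {
    out <- tibble(track = character(), seqid = character(),
                  start = integer(), end = integer(), class = character())
  }
  class(out) <- c("te_tracks", class(out))
  out
}
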
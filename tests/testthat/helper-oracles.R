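# Independent oracles used across the suite. These deliberately avoid the
# package's interval arithmetic: classification is done base by base on
# logical vectors, and distances by dynamic programming (utils::adist).

# logical coverage vector of an annotation on one sequence
coverage_vector <- function(ann, seqid, len) {
  v <- logical(len)
  rows <- ann[ann$seqid == seqid, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    v[rows$start[i]:rows$end[i]] <- TRUE
  }
  v
}

# brute-force per-base confusion counts over all sequences
confusion_oracle <- function(ref, pred, seq_lengths) {
  tp <- fp <- fn <- tn <- 0
  for (sid in names(seq_lengths)) {
    r <- coverage_vector(ref, sid, seq_lengths[[sid]])
    p <- coverage_vector(pred, sid, seq_lengths[[sid]])
    tp <- tp + sum(r & p)
    fp <- fp + sum(!r & p)
    fn <- fn + sum(r & !p)
    tn <- tn + sum(!r & !p)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Levenshtein distance by dynamic programming, independent of the
# mutation engine's event log
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# random annotation of roughly `n` intervals on one sequence
random_annotation <- function(len, n, seqid = "chr") {
  start <- sort(sample.int(len, n, replace = TRUE))
  width <- pmax(1L, rgeom(n, 1 / 50) + 1L)
  tibble::tibble(seqid = seqid, start = start,
                 end = pmin(len, start + width - 1L))
}

# annotation from a logical per-base vector (for random predictions)
annotation_from_vector <- function(v, seqid = "chr") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(seqid = seqid, start = starts[keep], end = ends[keep])
}
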
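#' Read an annotation from GFF3
#'
#' Wraps [rtracklayer::import()] and flattens the result into the
#' package's annotation tibble: `seqid`, `start`, `end`, `strand`,
#' `source`, `type`, plus one column per GFF attribute. Attributes written
#' by the simulator are normalised back onto the canonical columns
#' (`Family` -> `family`, `RealizedDivergence` -> `divergence`,
#' `TargetDivergence` -> `target_divergence`, `Truncated` -> `truncated`,
#' `NestedIn` -> `nested_in`); a bare `Divergence` or `Identity` attribute
#' from converted tool output is mapped to `divergence`/`identity`.
#' Records are sorted, and checked against `seq_lengths` when given.
#'
#' @param path GFF3 file path.
#' @param seq_lengths optional named sequence lengths for validation.
#' @return annotation tibble.
#' @export
read_gff <- function(path, seq_lengths = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tebench_input_error")
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      abort(paste0("cannot parse GFF3 ", path, ": ", conditionMessage(e)),
            class = "tebench_input_error")
    }
  )
  df <- as_tibble(as.data.frame(gr))
  df <- rename(df, seqid = "seqnames")
  df$strand <- as.character(df$strand)
  df$seqid <- as.character(df$seqid)
  renames <- c(Family = "family", RealizedDivergence = "divergence",
               TargetDivergence = "target_divergence",
               Truncated = "truncated", NestedIn = "nested_in",
               Divergence = "divergence", Identity = "identity")
  for (old in names(renames)) {
    new <- renames[[old]]
    if (old %in% names(df) && !new %in% names(df)) {
      df[[new]] <- df[[old]]
      df[[old]] <- NULL
    }
  }
  for (col in c("divergence", "target_divergence", "identity", "truncated")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  df$width <- NULL
  as_annotation(df, seq_lengths)
}

#' Write an annotation as GFF3
#'
#' Canonical columns are emitted as GFF columns (`source`, `type`,
#' `strand`; defaults `te-sim`/`dispersed_repeat` when absent) and the
#' remaining columns as attributes with capitalised simulator names
#' (`ID`, `Family`, `TargetDivergence`, `RealizedDivergence`, `Truncated`,
#' `NestedIn`). `seq_lengths` adds `##sequence-region` pragmas.
#'
#' @param x annotation tibble.
#' @param path output path.
#' @param seq_lengths optional named sequence lengths.
#' @return invisibly, `path`.
#' @export
write_gff <- function(x, path, seq_lengths = NULL) {
  x <- as_annotation(x, seq_lengths)
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else {
    "*"
  }
  gr <- GenomicRanges::GRanges(
    seqnames = x$seqid,
    ranges = IRanges::IRanges(x$start, x$end),
    strand = strand
  )
  S4Vectors::mcols(gr)$source <- if ("source" %in% names(x)) x$source else "te-sim"
  S4Vectors::mcols(gr)$type <- if ("type" %in% names(x)) x$type else
    "dispersed_repeat"
  attr_map <- c(ID = "ID", family = "Family",
                target_divergence = "TargetDivergence",
                divergence = "RealizedDivergence",
                truncated = "Truncated", nested_in = "NestedIn",
                identity = "Identity")
  for (col in names(attr_map)) {
    if (col %in% names(x)) {
      S4Vectors::mcols(gr)[[attr_map[[col]]]] <- x[[col]]
    }
  }
  extra <- setdiff(names(x), c("seqid", "start", "end", "strand", "source",
                               "type", names(attr_map)))
  for (col in extra) {
    S4Vectors::mcols(gr)[[col]] <- x[[col]]
  }
  if (!is.null(seq_lengths)) {
    sl <- as_seq_lengths(seq_lengths)
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Parse a RepeatMasker `.out` annotation
#'
#' Reads the fixed-layout `.out` table (3 header lines, then
#' whitespace-separated fields: score, %div, %del, %ins, query, begin,
#' end, (left), strand, repeat, class/family, ...). The `C` strand code is
#' mapped to `-` and the divergence column to the `divergence` attribute.
#'
#' @param path `.out` file path.
#' @return annotation tibble (`seqid`, `start`, `end`, `strand`,
#'   `family`, `class_family`, `divergence`, `score`, `source`).
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tebench_input_error")
  }
  lines <- readLines(path)
  body_idx <- which(nzchar(trimws(lines)))
  body_idx <- body_idx[body_idx > 3] # fixed 3-line header
  if (length(body_idx) == 0) {
    return(as_annotation(tibble(seqid = character(), start = integer(),
                                end = integer(), strand = character(),
                                family = character(),
                                class_family = character(),
                                divergence = numeric(), score = numeric(),
                                source = character())))
  }
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 11) {
      abort(paste0("malformed RepeatMasker record at line ", i, ": ",
                   length(f), " fields, expected >= 11."),
            class = "tebench_input_error")
    }
    tibble(seqid = f[5],
           start = as.integer(f[6]),
           end = as.integer(f[7]),
           strand = if (f[9] == "C") "-" else f[9],
           family = f[10],
           class_family = f[11],
           divergence = as.numeric(f[2]),
           score = as.numeric(f[1]),
           source = "RepeatMasker")
  })
  as_annotation(bind_rows(rows))
}

#' Convert a RepeatMasker `.out` file to GFF3
#'
#' Normalisation step for tool outputs: read with
#' [read_repeatmasker_out()], write with [write_gff()].
#'
#' @param path `.out` file path.
#' @param gff_path output GFF3 path.
#' @param seq_lengths optional named sequence lengths.
#' @return the annotation tibble, invisibly.
#' @export
repeatmasker_out_to_gff <- function(path, gff_path, seq_lengths = NULL) {
  ann <- read_repeatmasker_out(path)
  ann$type <- "dispersed_repeat"
  ann$source <- "RepeatMasker"
  write_gff(ann, gff_path, seq_lengths)
  invisible(ann)
}
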
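#' Read a (multi-)FASTA file of nucleotide sequences
#'
#' Identifiers are the first whitespace-delimited token of each header
#' (Dfam/RepBase-style headers are accepted). Case is preserved, so
#' soft-masked (lowercase) stretches survive a round trip; request an
#' uppercase view with `uppercase = TRUE`. Duplicate identifiers, empty
#' records and symbols outside {A,C,G,T,N} (either case) are rejected with
#' the offending line number.
#'
#' @param path FASTA file path.
#' @param uppercase return sequences uppercased (default `FALSE`).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tebench_input_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("cannot parse FASTA ", path, ": ", conditionMessage(e)),
            class = "tebench_input_error")
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA identifier(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "tebench_input_error")
  }
  bad <- which(!nzchar(seqs) | grepl("[^ACGTNacgtn]", seqs))
  if (length(bad)) {
    lines <- readLines(path)
    first_bad_line <- NA_integer_
    offending <- which(grepl("[^ACGTNacgtn]", lines) & !startsWith(lines, ">"))
    if (length(offending)) first_bad_line <- offending[1]
    abort(paste0(
      "record(s) ", paste(ids[bad], collapse = ", "),
      " empty or containing symbols outside {A,C,G,T,N}",
      if (!is.na(first_bad_line)) paste0(" (first at line ", first_bad_line, ")"),
      "."), class = "tebench_input_error")
  }
  out <- setNames(seqs, ids)
  if (uppercase) out <- toupper(out)
  out
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line width (default 60).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 60) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("sequences must be named.", class = "tebench_input_error")
  }
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read sequence lengths from a FASTA index or a FASTA file
#'
#' Accepts a `samtools faidx`-style TSV (first two columns: name, length)
#' or a FASTA file (lengths computed from the records).
#'
#' @param path file path.
#' @return named numeric vector of sequence lengths.
#' @export
read_seq_lengths <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tebench_input_error")
  }
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    return(Biostrings::fasta.seqlengths(path) |>
             (\(x) setNames(as.numeric(x), sub("\\s.*$", "", names(x))))())
  }
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2 || !is.numeric(df[[2]])) {
    abort("expected a two-column name/length TSV or a FASTA file.",
          class = "tebench_input_error")
  }
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
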
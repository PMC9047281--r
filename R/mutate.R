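#' Generate a random base sequence with a given GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1 - gc)/2. This sequence is the TE-free background into
#' which copies are later inserted.
#'
#' @param length sequence length in bases (> 0).
#' @param gc GC fraction in \[0, 1\].
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @return a single nucleotide string.
#' @export
#' @examples
#' generate_base_sequence(50, gc = 0.42, seed = 1)
generate_base_sequence <- function(length, gc = 0.42, seed = NULL) {
  if (!is.numeric(length) || length(length) != 1 || length < 1) {
    abort("`length` must be a positive number.", class = "tebench_input_error")
  }
  if (!is.numeric(gc) || gc < 0 || gc > 1) {
    abort("`gc` must lie in [0, 1].", class = "tebench_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  paste(bases, collapse = "")
}

#' Reverse-complement a nucleotide string
#'
#' @param seq nucleotide string over {A,C,G,T,N} (either case).
#' @return the reverse complement, case preserved.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Largest-remainder apportionment of `n` events over `weights`.
apportion <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Mutate a TE copy towards a target divergence
#'
#' Draws `round(target_divergence * length)` mutation events, partitions
#' them into substitutions, insertions and deletions by `weights`
#' (largest-remainder rounding, so substitution-only settings give exactly
#' the event count as substitutions), and applies them at distinct anchor
#' positions. Substitutions replace a base with a uniformly chosen
#' different base; indel lengths are geometric with mean
#' `indel_mean_length`. Each event consumes budget equal to its edit cost
#' (1 per substituted, inserted or deleted base); events are trimmed or
#' dropped once the budget is spent, so the realized divergence — the edit
#' cost of the applied script divided by the consensus length — never
#' exceeds `target_divergence`. Consensus `N` bases are never mutated.
#'
#' @param consensus nucleotide string (non-empty).
#' @param target_divergence divergence ceiling as a fraction in \[0, 1\].
#' @param weights substitution/insertion/deletion weights.
#' @param indel_mean_length mean indel length in bases.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return a list with `seq` (mutated string), `realized_divergence`
#'   (fraction) and `log` (tibble of applied events: anchor position on the
#'   consensus, type, edit cost in bases).
#' @export
mutate_copy <- function(consensus, target_divergence,
                        weights = c(0.8, 0.1, 0.1),
                        indel_mean_length = 3,
                        seed = NULL) {
  if (!nzchar(consensus)) {
    abort("`consensus` must be non-empty.", class = "tebench_input_error")
  }
  if (target_divergence < 0 || target_divergence > 1) {
    abort("`target_divergence` must lie in [0, 1].",
          class = "tebench_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  res <- mutate_chars(chars, target_divergence, weights, indel_mean_length)
  list(seq = res$seq,
       realized_divergence = res$cost / length(chars),
       log = res$log)
}

# Core mutation engine on a character vector; returns the mutated string,
# the total edit cost and the event log. Uses the current RNG stream.
mutate_chars <- function(chars, target_divergence, weights, indel_mean) {
  len <- length(chars)
  budget <- round(target_divergence * len)
  # round() may overshoot the cap by half an event; clamp to keep the
  # realized divergence at or below the target
  if (budget / len > target_divergence) budget <- floor(target_divergence * len)
  empty_log <- tibble(position = integer(), type = character(),
                      cost = integer())
  if (budget == 0) {
    return(list(seq = paste(chars, collapse = ""), cost = 0L, log = empty_log))
  }
  eligible <- which(chars %in% c("A", "C", "G", "T", "a", "c", "g", "t"))
  n_events <- min(budget, length(eligible))
  if (n_events == 0) {
    return(list(seq = paste(chars, collapse = ""), cost = 0L, log = empty_log))
  }
  counts <- apportion(n_events, weights)
  anchors <- sort(sample(eligible, n_events))
  types <- sample(rep(c("sub", "ins", "del"), counts))
  # gap to the next anchor caps deletion length, so events never interact
  gaps <- c(diff(anchors), len - anchors[n_events] + 1L)

  tokens <- chars
  remaining <- budget
  p_geom <- 1 / indel_mean
  log_pos <- integer(n_events)
  log_type <- character(n_events)
  log_cost <- integer(n_events)
  alphabet <- c("A", "C", "G", "T")
  for (i in seq_len(n_events)) {
    if (remaining <= 0) break
    a <- anchors[i]
    if (types[i] == "sub") {
      cur <- toupper(tokens[a])
      tokens[a] <- sample(setdiff(alphabet, cur), 1)
      cost <- 1L
    } else if (types[i] == "ins") {
      l <- min(rgeom(1, p_geom) + 1L, remaining)
      ins <- paste(sample(alphabet, l, replace = TRUE), collapse = "")
      tokens[a] <- paste0(tokens[a], ins)
      cost <- l
    } else {
      l <- min(rgeom(1, p_geom) + 1L, remaining, gaps[i])
      tokens[a:(a + l - 1L)] <- ""
      cost <- l
    }
    remaining <- remaining - cost
    log_pos[i] <- a
    log_type[i] <- types[i]
    log_cost[i] <- cost
  }
  applied <- log_cost > 0L
  list(seq = paste(tokens, collapse = ""),
       cost = sum(log_cost),
       log = tibble(position = log_pos[applied], type = log_type[applied],
                    cost = log_cost[applied]))
}

#' Truncate a TE copy at its 5' end
#'
#' Models fragmented insertions: a uniformly drawn share u ~ U(0, fraction]
#' of the copy length is removed from the 5' end. For minus-strand copies
#' apply this before reverse-complementing, so the loss is on the element's
#' own 5' end.
#'
#' @param seq nucleotide string.
#' @param fraction maximum removable share of the length, in \[0, 1\];
#'   `0` returns the input unchanged.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return list with `seq` (truncated string) and `truncated_bases`.
#' @export
truncate_copy <- function(seq, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1) {
    abort("`fraction` must lie in [0, 1].", class = "tebench_input_error")
  }
  if (fraction == 0) {
    return(list(seq = seq, truncated_bases = 0L))
  }
  if (!is.null(seed)) set.seed(seed)
  len <- nchar(seq)
  u <- fraction * (1 - runif(1)) # Uniform(0, fraction]
  cut <- min(round(u * len), len - 1L)
  list(seq = substr(seq, cut + 1L, len), truncated_bases = as.integer(cut))
}
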
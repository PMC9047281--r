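#' Generate mutated (and possibly truncated) copies for every family
#'
#' For each family the configured number of copies is drawn: each copy is
#' mutated towards the family's divergence target, a `fragment_fraction`
#' share is 5'-truncated by up to `max_truncation` of its length, a strand
#' is picked uniformly, and minus-strand copies are reverse-complemented
#' (after truncation, so the loss is on the element's own 5' end). Every
#' family runs on its own RNG stream derived from `seed`, so families are
#' independently replayable.
#'
#' @param config a [simulation_config()].
#' @return tibble of copies: `copy_uid`, `family_id`, `copy_index`,
#'   `strand`, `target_divergence`, `realized_divergence` (fractions),
#'   `truncated_bases`, `length`, `seq`, `nesting_fraction`.
#' @export
generate_copies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fams <- config$families
  purrr::pmap_dfr(fams, function(family_id, consensus, copies,
                                 target_divergence, fragment_fraction,
                                 max_truncation, nesting_fraction) {
    set.seed(derive_seed(config$seed, paste0("copies/", family_id)))
    chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
    n <- copies
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_frag <- round(fragment_fraction * n)
    frag_idx <- if (n_frag > 0) sample(n, n_frag) else integer()
    out <- vector("list", n)
    for (i in seq_len(n)) {
      m <- mutate_chars(chars, target_divergence, config$mutation_weights,
                        config$indel_mean_length)
      s <- m$seq
      tb <- 0L
      if (i %in% frag_idx && max_truncation > 0) {
        tr <- truncate_copy(s, max_truncation)
        s <- tr$seq
        tb <- tr$truncated_bases
      }
      if (strand[i] == "-") s <- revcomp(s)
      out[[i]] <- tibble(
        copy_uid = paste0(family_id, "#", i),
        family_id = family_id,
        copy_index = i,
        strand = strand[i],
        target_divergence = target_divergence,
        realized_divergence = m$cost / length(chars),
        truncated_bases = tb,
        length = nchar(s),
        seq = s,
        nesting_fraction = nesting_fraction
      )
    }
    bind_rows(out)
  })
}

#' Plan insertion positions for a set of copies
#'
#' Each copy is assigned either a uniformly random, distinct offset in the
#' base sequence, or — for a per-family `nesting_fraction` share of copies
#' — a uniformly random position strictly inside a previously placed copy
#' of a different family. Nesting depth is 1: a nested copy never hosts
#' another. Offsets count the bases of the target sequence preceding the
#' insertion point (an offset of 50 inserts after base 50).
#'
#' @param copies tibble from [generate_copies()] (needs `copy_uid`,
#'   `family_id`, `length` and `nesting_fraction`).
#' @param base_length length of the base sequence the plan applies to.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return the `copies` tibble with columns `nested_in` (host `copy_uid`
#'   or `NA`) and `offset` (base frame for top-level copies, host frame
#'   for nested ones), ordered family by family as planned.
#' @export
plan_insertions <- function(copies, base_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  copies <- as_tibble(copies)
  n <- nrow(copies)
  nested <- logical(n)
  for (fam in unique(copies$family_id)) {
    idx <- which(copies$family_id == fam)
    k <- round(copies$nesting_fraction[idx[1]] * length(idx))
    if (k > 0) nested[if (k == length(idx)) idx else sample(idx, k)] <- TRUE
  }
  n_top <- sum(!nested)
  if (n_top > base_length) {
    abort("more top-level copies than distinct insertion offsets in the base sequence.",
          class = "tebench_capacity_error")
  }
  offset <- integer(n)
  host <- rep(NA_character_, n)
  offset[!nested] <- sample.int(base_length, n_top)
  if (any(nested)) {
    hosts <- copies[!nested & copies$length >= 2, , drop = FALSE]
    for (i in which(nested)) {
      eligible <- hosts[hosts$family_id != copies$family_id[i], , drop = FALSE]
      if (nrow(eligible) == 0) {
        abort(paste0("no eligible host for nested copy ", copies$copy_uid[i],
                     ": need a placed copy of a different family."),
              class = "tebench_capacity_error")
      }
      j <- sample.int(nrow(eligible), 1)
      host[i] <- eligible$copy_uid[j]
      offset[i] <- sample.int(eligible$length[j] - 1L, 1) # strictly inside
    }
  }
  copies$nested_in <- host
  copies$offset <- offset
  copies
}

# Splice child sequences into a host at the given internal offsets.
# Returns the expanded sequence plus 0-based half-open intervals, one or
# more for the host (split around the children) and one per child.
splice_children <- function(host_uid, host_seq, children) {
  children <- children[order(children$offset, children$copy_uid), ,
                       drop = FALSE]
  len <- nchar(host_seq)
  cuts <- c(0L, children$offset)
  ends <- c(children$offset, len)
  parts <- character(0)
  ivs <- list()
  pos <- 0L
  for (k in seq_len(nrow(children) + 1L)) {
    frag_len <- ends[k] - cuts[k]
    if (frag_len > 0) {
      parts <- c(parts, substr(host_seq, cuts[k] + 1L, ends[k]))
      ivs[[length(ivs) + 1L]] <- tibble(copy_uid = host_uid,
                                        rel_start = pos,
                                        rel_end = pos + frag_len)
      pos <- pos + frag_len
    }
    if (k <= nrow(children)) {
      cl <- children$length[k]
      parts <- c(parts, children$seq[k])
      ivs[[length(ivs) + 1L]] <- tibble(copy_uid = children$copy_uid[k],
                                        rel_start = pos,
                                        rel_end = pos + cl)
      pos <- pos + cl
    }
  }
  list(seq = paste(parts, collapse = ""), intervals = bind_rows(ivs))
}

#' Assemble the simulated genome from a base sequence and a placement plan
#'
#' Insertions expand the sequence: nothing is overwritten, and every
#' coordinate downstream of an insertion shifts by the inserted length.
#' A host copy split by a nested insertion is reported as two (or more)
#' intervals sharing one copy identifier.
#'
#' @param base base nucleotide string.
#' @param plan tibble from [plan_insertions()].
#' @param seqid sequence name for the ground-truth annotation.
#' @return an object of class `simulated_genome`: fields `sequence`,
#'   `seqid`, `base_length`, `copies` (the plan) and `ground_truth`
#'   (annotation tibble, 1-based inclusive coordinates, divergence
#'   attributes in percent).
#' @export
assemble_genome <- function(base, plan, seqid = "sim") {
  base_len <- nchar(base)
  top <- plan[is.na(plan$nested_in), , drop = FALSE]
  top <- top[order(top$offset, top$copy_uid), , drop = FALSE]
  if (anyDuplicated(top$offset)) {
    abort("top-level insertion offsets must be distinct.",
          class = "tebench_internal_error")
  }
  if (nrow(top) > 0 && (min(top$offset) < 1 || max(top$offset) > base_len)) {
    abort("insertion offsets outside the base sequence.",
          class = "tebench_internal_error")
  }
  orphan <- !is.na(plan$nested_in) & !(plan$nested_in %in% top$copy_uid)
  if (any(orphan)) {
    abort("nested copies reference hosts missing from the plan.",
          class = "tebench_internal_error")
  }

  units <- vector("list", nrow(top))
  for (k in seq_len(nrow(top))) {
    uid <- top$copy_uid[k]
    kids <- plan[!is.na(plan$nested_in) & plan$nested_in == uid, ,
                 drop = FALSE]
    if (nrow(kids) == 0) {
      units[[k]] <- list(seq = top$seq[k],
                         intervals = tibble(copy_uid = uid, rel_start = 0L,
                                            rel_end = top$length[k]))
    } else {
      units[[k]] <- splice_children(uid, top$seq[k], kids)
    }
  }

  unit_len <- vapply(units, function(u) nchar(u$seq), integer(1))
  offs <- top$offset
  starts0 <- offs + c(0L, cumsum(unit_len))[seq_along(offs)]

  seg_start <- c(1L, offs + 1L)
  seg_end <- c(offs, base_len)
  base_segs <- substring(base, seg_start, seg_end)
  pieces <- character(2L * length(units) + 1L)
  pieces[seq(1, length(pieces), by = 2)] <- base_segs
  if (length(units)) {
    pieces[seq(2, length(pieces) - 1, by = 2)] <-
      vapply(units, `[[`, character(1), "seq")
  }
  genome <- paste(pieces, collapse = "")

  gt <- purrr::map2_dfr(units, starts0, function(u, s0) {
    dplyr::mutate(u$intervals, start = s0 + .data$rel_start + 1L,
                  end = s0 + .data$rel_end)
  })
  if (nrow(gt) > 0) {
    meta <- plan[, c("copy_uid", "family_id", "strand", "target_divergence",
                     "realized_divergence", "truncated_bases", "nested_in")]
    gt <- left_join(gt, meta, by = "copy_uid")
    gt <- tibble(
      seqid = seqid,
      start = gt$start,
      end = gt$end,
      strand = gt$strand,
      family = gt$family_id,
      divergence = 100 * gt$realized_divergence,
      target_divergence = 100 * gt$target_divergence,
      truncated = gt$truncated_bases,
      nested_in = gt$nested_in,
      ID = gt$copy_uid,
      source = "te-sim",
      type = "dispersed_repeat"
    )
    gt <- arrange(gt, .data$seqid, .data$start, .data$end)
  } else {
    gt <- empty_annotation(seqid)
  }

  structure(
    list(sequence = genome, seqid = seqid, base_length = base_len,
         copies = plan, ground_truth = gt),
    class = "simulated_genome"
  )
}

empty_annotation <- function(seqid = character()) {
  tibble(seqid = character(), start = integer(), end = integer(),
         strand = character(), family = character(), divergence = numeric(),
         target_divergence = numeric(), truncated = integer(),
         nested_in = character(), ID = character(), source = character(),
         type = character())
}

#' Simulate a genome with known TE content
#'
#' End-to-end composition: generates the random base sequence, draws
#' mutated/truncated/nested copies for every family, plans their
#' placement, and assembles the final sequence together with an exact
#' ground-truth annotation. Fully deterministic given the configuration's
#' master seed.
#'
#' @param config a [simulation_config()].
#' @return a `simulated_genome`; see [assemble_genome()]. Use [glance()]
#'   for the run summary and [write_simulation()] to emit FASTA + GFF3.
#' @export
#' @examples
#' fam <- family_spec("toy", generate_base_sequence(400, 0.5, seed = 7),
#'                    copies = 5, target_divergence = 0.1)
#' sim <- simulate_genome(simulation_config(fam, base_length = 5000,
#'                                          seed = 42))
#' glance(sim)
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  base <- generate_base_sequence(config$base_length, config$gc_content,
                                 seed = derive_seed(config$seed, "base"))
  copies <- generate_copies(config)
  plan <- plan_insertions(copies, config$base_length,
                          seed = derive_seed(config$seed, "plan"))
  sim <- assemble_genome(base, plan, seqid = config$seqid)
  sim$config <- config
  sim
}

#' @export
print.simulated_genome <- function(x, ...) {
  g <- glance(x)
  cat("<simulated_genome>", x$seqid, "\n")
  cat(sprintf("  length %s bp (base %s bp), %d TE copies from %d families\n",
              format(g$length, big.mark = ","),
              format(g$base_length, big.mark = ","),
              g$n_copies, g$n_families))
  cat(sprintf("  TE bases: %s (%.2f%%)\n",
              format(g$te_bases, big.mark = ","), g$te_percent))
  invisible(x)
}

#' @describeIn simulate_genome one-row run summary: final length, base
#'   length, TE bases and percent, realized GC percent, copy and family
#'   counts.
#' @param x a `simulated_genome`.
#' @param ... unused.
#' @export
glance.simulated_genome <- function(x, ...) {
  te_bases <- sum(x$ground_truth$end - x$ground_truth$start + 1)
  len <- nchar(x$sequence)
  tibble(
    length = len,
    base_length = x$base_length,
    te_bases = te_bases,
    te_percent = 100 * te_bases / len,
    gc_percent = gc_percent(x$sequence),
    n_copies = nrow(x$copies),
    n_families = length(unique(x$copies$family_id))
  )
}

#' @describeIn simulate_genome per-copy table (sequence column dropped).
#' @export
tidy.simulated_genome <- function(x, ...) {
  dplyr::select(x$copies, -"seq")
}

#' Realized G+C percentage of a nucleotide string
#'
#' @param seq nucleotide string.
#' @return percent of G and C among A/C/G/T bases.
#' @export
gc_percent <- function(seq) {
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(toupper(seq)))
  100 * sum(f[c("G", "C")]) / sum(f[c("A", "C", "G", "T")])
}

#' Write a simulated genome to disk
#'
#' Emits `<prefix>.fasta` (60-column wrapped), `<prefix>.gff3` (ground
#' truth) and `<prefix>.summary.tsv` (the [glance()] row), plus a JSON run
#' manifest recording seed and file digests.
#'
#' @param sim a `simulated_genome`.
#' @param out_prefix output path prefix.
#' @return invisibly, a named vector of the files written.
#' @export
write_simulation <- function(sim, out_prefix) {
  stopifnot(inherits(sim, "simulated_genome"))
  paths <- c(fasta = paste0(out_prefix, ".fasta"),
             gff = paste0(out_prefix, ".gff3"),
             summary = paste0(out_prefix, ".summary.tsv"))
  write_fasta(setNames(sim$sequence, sim$seqid), paths[["fasta"]])
  write_gff(sim$ground_truth, paths[["gff"]],
            seq_lengths = setNames(nchar(sim$sequence), sim$seqid))
  readr::write_tsv(glance(sim), paths[["summary"]])
  seed <- if (!is.null(sim$config)) sim$config$seed else NA_integer_
  write_run_manifest(paste0(out_prefix, ".manifest.json"), seed = seed,
                     outputs = paths,
                     config = if (!is.null(sim$config)) {
                       sim$config[c("base_length", "gc_content", "seed")]
                     })
  invisible(paths)
}
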
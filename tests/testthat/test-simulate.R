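test_that("base sequence respects length, GC limits and the configured GC", {
  s0 <- generate_base_sequence(1000, gc = 0, seed = 1)
  expect_equal(nchar(s0), 1000)
  expect_false(grepl("[GC]", s0))
  s1 <- generate_base_sequence(1000, gc = 1, seed = 1)
  expect_false(grepl("[AT]", s1))

  n <- 1e5
  gc <- 0.42
  s <- generate_base_sequence(n, gc = gc, seed = 42)
  sigma <- sqrt(gc * (1 - gc) / n)
  expect_lt(abs(gc_percent(s) / 100 - gc), 3 * sigma)

  expect_error(generate_base_sequence(0, 0.5), class = "tebench_input_error")
  expect_error(generate_base_sequence(10, 1.2), class = "tebench_input_error")
})

test_that("base sequence generation is deterministic given a seed", {
  expect_identical(generate_base_sequence(5000, 0.45, seed = 7),
                   generate_base_sequence(5000, 0.45, seed = 7))
})

test_that("substitution-only mutation hits the exact event count", {
  m <- mutate_copy("ACGTACGTAC", 0.2, weights = c(1, 0, 0), seed = 3)
  expect_equal(nchar(m$seq), 10)
  ham <- sum(strsplit("ACGTACGTAC", "")[[1]] != strsplit(m$seq, "")[[1]])
  expect_equal(ham, 2)
  expect_equal(edit_distance("ACGTACGTAC", m$seq), 2)
  expect_equal(m$realized_divergence, 0.2)
  expect_equal(nrow(m$log), 2)
})

test_that("zero target divergence returns the input unchanged", {
  cons <- generate_base_sequence(500, 0.5, seed = 2)
  m <- mutate_copy(cons, 0)
  expect_identical(m$seq, cons)
  expect_equal(m$realized_divergence, 0)
})

test_that("realized divergence never exceeds the target and bounds the DP distance", {
  set.seed(31)
  for (target in c(0.05, 0.15, 0.3)) {
    cons <- generate_base_sequence(800, 0.45)
    m <- mutate_copy(cons, target)
    expect_lte(m$realized_divergence, target)
    d <- edit_distance(cons, m$seq) / nchar(cons)
    expect_lte(d, m$realized_divergence + 1e-12)
    expect_gt(d, 0)
  }
})

test_that("sparse mutation events cost exactly their DP edit distance", {
  # at low event density events do not interact, so the logged edit cost
  # equals the Levenshtein distance computed independently
  set.seed(17)
  for (rep in 1:5) {
    cons <- generate_base_sequence(1000, 0.5)
    m <- mutate_copy(cons, 0.02)
    expect_equal(edit_distance(cons, m$seq), sum(m$log$cost))
  }
})

test_that("consensus N bases pass through mutation untouched", {
  cons <- paste0(strrep("N", 20), strrep("A", 100))
  set.seed(4)
  m <- mutate_copy(cons, 0.3, weights = c(1, 0, 0))
  expect_identical(substr(m$seq, 1, 20), strrep("N", 20))
})

test_that("truncation removes the expected share from the 5' end", {
  expect_identical(truncate_copy("ACGT", 0),
                   list(seq = "ACGT", truncated_bases = 0L))

  seq311 <- generate_base_sequence(311, 0.5, seed = 9)
  set.seed(21)
  for (i in 1:20) {
    tr <- truncate_copy(seq311, 0.3)
    expect_gte(nchar(tr$seq), 218) # 311 - round(0.3 * 311)
    expect_identical(tr$seq, substr(seq311, tr$truncated_bases + 1, 311))
  }

  # mean of Uniform(0, 0.5] * 100 is 25
  set.seed(33)
  s100 <- strrep("A", 100)
  cuts <- replicate(1000, truncate_copy(s100, 0.5)$truncated_bases)
  expect_lt(abs(mean(cuts) - 25), 3 * sd(cuts) / sqrt(1000))
})

test_that("placement gives distinct offsets, is deterministic, and nests where asked", {
  cfg <- tiny_config(copies = 10)
  copies <- generate_copies(cfg)
  p1 <- plan_insertions(copies, cfg$base_length, seed = 8)
  p2 <- plan_insertions(copies, cfg$base_length, seed = 8)
  expect_identical(p1, p2)
  top <- p1[is.na(p1$nested_in), ]
  expect_false(anyDuplicated(top$offset) > 0)
  expect_true(all(top$offset >= 1 & top$offset <= cfg$base_length))

  # family B fully nested inside other families' copies
  lib <- tiny_library(2)
  fams <- dplyr::bind_rows(
    family_spec("A", lib[[1]], copies = 5),
    family_spec("B", lib[[2]], copies = 4, nesting_fraction = 1))
  cfgn <- simulation_config(fams, base_length = 10000, seed = 2)
  cpn <- generate_copies(cfgn)
  pn <- plan_insertions(cpn, 10000, seed = 3)
  b <- pn[pn$family_id == "B", ]
  expect_true(all(!is.na(b$nested_in)))
  expect_true(all(grepl("^A#", b$nested_in)))
  host_len <- pn$length[match(b$nested_in, pn$copy_uid)]
  expect_true(all(b$offset >= 1 & b$offset <= host_len - 1))
})

test_that("placement errors on impossible demands", {
  cfg <- tiny_config(copies = 10)
  copies <- generate_copies(cfg)
  expect_error(plan_insertions(copies, base_length = 5, seed = 1),
               class = "tebench_capacity_error")
  lib <- tiny_library(1)
  fams <- family_spec("solo", lib[[1]], copies = 4, nesting_fraction = 1)
  solo <- generate_copies(simulation_config(fams, 10000, seed = 1))
  expect_error(plan_insertions(solo, 10000, seed = 1),
               class = "tebench_capacity_error")
})

test_that("assembly splices by expansion with exact coordinates", {
  base <- generate_base_sequence(100, 0.5, seed = 6)
  plan <- tibble::tibble(
    copy_uid = "fam#1", family_id = "fam", copy_index = 1L, strand = "+",
    target_divergence = 0, realized_divergence = 0, truncated_bases = 0L,
    length = 10L, seq = strrep("G", 10), nesting_fraction = 0,
    nested_in = NA_character_, offset = 50L)
  sim <- assemble_genome(base, plan, seqid = "s")
  expect_equal(nchar(sim$sequence), 110)
  expect_equal(sim$ground_truth$start, 51)
  expect_equal(sim$ground_truth$end, 60)
  expect_identical(substr(sim$sequence, 1, 50), substr(base, 1, 50))
  expect_identical(substr(sim$sequence, 51, 60), strrep("G", 10))
  expect_identical(substr(sim$sequence, 61, 110), substr(base, 51, 100))
})

test_that("assembly with no insertions returns the base and empty truth", {
  base <- generate_base_sequence(200, 0.5, seed = 1)
  plan <- tibble::tibble(
    copy_uid = character(), family_id = character(), copy_index = integer(),
    strand = character(), target_divergence = numeric(),
    realized_divergence = numeric(), truncated_bases = integer(),
    length = integer(), seq = character(), nesting_fraction = numeric(),
    nested_in = character(), offset = integer())
  sim <- assemble_genome(base, plan)
  expect_identical(sim$sequence, base)
  expect_equal(nrow(sim$ground_truth), 0)
})

test_that("a nested insertion splits its host into flanking intervals", {
  base <- strrep("T", 40)
  plan <- tibble::tibble(
    copy_uid = c("A#1", "B#1"), family_id = c("A", "B"),
    copy_index = c(1L, 1L), strand = "+",
    target_divergence = 0, realized_divergence = 0, truncated_bases = 0L,
    length = c(20L, 10L), seq = c(strrep("A", 20), strrep("C", 10)),
    nesting_fraction = 0, nested_in = c(NA, "A#1"), offset = c(10L, 5L))
  sim <- assemble_genome(base, plan)
  gt <- sim$ground_truth
  a <- gt[gt$ID == "A#1", ]
  b <- gt[gt$ID == "B#1", ]
  expect_equal(nrow(a), 2) # host split in two
  expect_equal(a$end - a$start + 1, c(5, 15))
  expect_equal(nrow(b), 1)
  expect_equal(b$end - b$start + 1, 10)
  # B sits exactly between the two A fragments
  expect_equal(b$start, a$end[1] + 1)
  expect_equal(b$end, a$start[2] - 1)
  expect_identical(substr(sim$sequence, b$start, b$end), strrep("C", 10))
  expect_equal(nchar(sim$sequence), 40 + 20 + 10)
})

test_that("simulation conserves length and area, caps divergence, reproduces", {
  cfg <- tiny_config(seed = 19, copies = 10, fragment_fraction = 0.3,
                     nesting_fraction = 0.2)
  sim <- simulate_genome(cfg)
  g <- glance(sim)
  # length conservation: base + sum of post-truncation copy lengths
  expect_equal(g$length, cfg$base_length + sum(sim$copies$length))
  # ground-truth area equals inserted copy bases (nesting splits, never overlaps)
  expect_equal(g$te_bases, sum(sim$copies$length))
  # divergence cap
  expect_true(all(sim$copies$realized_divergence <=
                    sim$copies$target_divergence + 1e-12))
  # byte-identical reproduction
  sim2 <- simulate_genome(cfg)
  expect_identical(sim$sequence, sim2$sequence)
  expect_identical(sim$ground_truth, sim2$ground_truth)
})

test_that("ground-truth intervals are disjoint, sorted and in range", {
  cfg <- tiny_config(seed = 23, copies = 12, nesting_fraction = 0.25)
  sim <- simulate_genome(cfg)
  gt <- sim$ground_truth
  expect_true(all(gt$start >= 1 & gt$end <= nchar(sim$sequence)))
  expect_true(!is.unsorted(gt$start))
  expect_true(all(gt$start[-1] > gt$end[-nrow(gt)])) # pairwise disjoint
})

test_that("written FASTA and GFF are byte-identical across runs", {
  cfg <- tiny_config(seed = 29, copies = 5, base_length = 10000)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(simulate_genome(cfg), d1)
  write_simulation(simulate_genome(cfg), d2)
  expect_identical(readLines(paste0(d1, ".fasta")),
                   readLines(paste0(d2, ".fasta")))
  g1 <- readLines(paste0(d1, ".gff3"))
  g2 <- readLines(paste0(d2, ".gff3"))
  expect_identical(g1[!startsWith(g1, "##date")],
                   g2[!startsWith(g2, "##date")])
})

test_that("family specs are validated", {
  expect_error(family_spec("x", "ACGT", copies = 0),
               class = "tebench_input_error")
  expect_error(family_spec("x", "ACXT", copies = 1),
               class = "tebench_input_error")
  expect_error(family_spec("x", "ACGT", copies = 1, target_divergence = 1.5),
               class = "tebench_input_error")
  expect_error(simulation_config(family_spec("x", "ACGT", 1), base_length = 0),
               class = "tebench_input_error")
})
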
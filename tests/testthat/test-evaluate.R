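ann <- function(...) {
  tibble::tibble(seqid = "chr", ...)
}

test_that("merging handles overlap, adjacency and containment", {
  expect_equal(merge_intervals(ann(start = c(1, 5), end = c(10, 20)))[, c("start", "end")],
               tibble::tibble(start = 1L, end = 20L))
  # bookended adjacency
  expect_equal(merge_intervals(ann(start = c(1, 11), end = c(10, 20)))[, c("start", "end")],
               tibble::tibble(start = 1L, end = 20L))
  # containment
  expect_equal(merge_intervals(ann(start = c(1, 5), end = c(20, 10)))[, c("start", "end")],
               tibble::tibble(start = 1L, end = 20L))
  # separated intervals stay apart at max_gap 0
  out <- merge_intervals(ann(start = c(1, 13), end = c(10, 20)))
  expect_equal(nrow(out), 2)
  # ... and merge once the gap allowance covers them
  out2 <- merge_intervals(ann(start = c(1, 13), end = c(10, 20)), max_gap = 2)
  expect_equal(nrow(out2), 1)
  expect_error(merge_intervals(ann(start = 1, end = 2), max_gap = -1),
               class = "tebench_input_error")
})

test_that("merging is idempotent, order-insensitive and conserves covered bases", {
  set.seed(101)
  for (i in 1:20) {
    x <- random_annotation(5000, 30)
    m1 <- merge_intervals(x)
    expect_identical(m1[, c("seqid", "start", "end")],
                     merge_intervals(m1)[, c("seqid", "start", "end")])
    shuffled <- x[sample(nrow(x)), ]
    expect_identical(m1[, c("start", "end")],
                     merge_intervals(shuffled)[, c("start", "end")])
    expect_equal(sum(coverage_vector(m1, "chr", 5000)),
                 sum(coverage_vector(x, "chr", 5000)))
  }
})

test_that("merged attributes concatenate member values", {
  x <- ann(start = c(1, 5), end = c(10, 20))
  x$family <- c("Alu", "L1")
  out <- merge_intervals(x)
  expect_identical(out$family, "Alu,L1")
  expect_equal(out$n_merged, 2L)
})

test_that("confusion matrix matches the hand-worked quarter split", {
  cm <- confusion_matrix(ann(start = 1, end = 50), ann(start = 26, end = 75),
                         c(chr = 100))
  expect_equal(cm$tp, 25)
  expect_equal(cm$fp, 25)
  expect_equal(cm$fn, 25)
  expect_equal(cm$tn, 25)
  expect_equal(mcc(cm), 0)
})

test_that("identity and empty predictions classify correctly", {
  r <- ann(start = 1, end = 50)
  cm <- confusion_matrix(r, r, c(chr = 100))
  expect_equal(cm$fp, 0)
  expect_equal(cm$fn, 0)
  expect_equal(mcc(cm), 1)

  cm0 <- confusion_matrix(r, r[0, ], c(chr = 100))
  expect_equal(unlist(cm0[c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 0, fn = 50, tn = 50))
})

test_that("interval confusion matrix equals the per-base oracle on random fixtures", {
  set.seed(202)
  for (i in 1:30) {
    len <- sample(1000:20000, 1)
    sl <- c(chr = len)
    ref <- random_annotation(len, sample(5:40, 1))
    pred <- random_annotation(len, sample(5:40, 1))
    cm <- confusion_matrix(ref, pred, sl)
    oracle <- confusion_oracle(ref, pred, sl)
    expect_equal(cm[c("tp", "fp", "fn", "tn")], oracle)
    expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, len)
  }
})

test_that("swapping reference and prediction swaps FP and FN, MCC unchanged", {
  set.seed(303)
  for (i in 1:10) {
    len <- 5000
    ref <- random_annotation(len, 20)
    pred <- random_annotation(len, 20)
    a <- confusion_matrix(ref, pred, c(chr = len))
    b <- confusion_matrix(pred, ref, c(chr = len))
    expect_equal(a$fp, b$fn)
    expect_equal(a$fn, b$fp)
    expect_equal(mcc(a), mcc(b))
  }
})

test_that("multiple sequences are summed and validated", {
  sl <- c(c1 = 100, c2 = 200)
  ref <- tibble::tibble(seqid = c("c1", "c2"), start = c(1, 1), end = c(50, 100))
  pred <- tibble::tibble(seqid = "c1", start = 1, end = 50)
  cm <- confusion_matrix(ref, pred, sl)
  expect_equal(cm$tp, 50)
  expect_equal(cm$fn, 100)
  expect_equal(cm$tn, 150)
  expect_error(confusion_matrix(tibble::tibble(seqid = "cX", start = 1, end = 5),
                                pred, sl),
               class = "tebench_input_error")
  expect_error(confusion_matrix(tibble::tibble(seqid = "c1", start = 1, end = 500),
                                pred, sl),
               class = "tebench_input_error")
})

test_that("MCC boundary values and degenerate convention", {
  expect_equal(mcc(list(tp = 50, fp = 0, fn = 0, tn = 50)), 1)
  expect_equal(mcc(list(tp = 0, fp = 50, fn = 50, tn = 0)), -1)
  d <- mcc(list(tp = 0, fp = 0, fn = 0, tn = 100))
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
  # cross-check against the Pearson correlation of the 0/1 base vectors
  set.seed(7)
  len <- 2000
  ref <- random_annotation(len, 15)
  pred <- random_annotation(len, 15)
  cm <- confusion_matrix(ref, pred, c(chr = len))
  r <- coverage_vector(ref, "chr", len)
  p <- coverage_vector(pred, "chr", len)
  expect_equal(mcc(cm), cor(as.numeric(r), as.numeric(p)), tolerance = 1e-12)
})

test_that("eval_metrics derives sensitivity, specificity, precision, F1", {
  m <- eval_metrics(list(tp = 40, fp = 10, fn = 20, tn = 30))
  expect_equal(m$sensitivity, 40 / 60)
  expect_equal(m$specificity, 30 / 40)
  expect_equal(m$precision, 40 / 50)
  expect_equal(m$f1, 2 * (0.8 * (2 / 3)) / (0.8 + 2 / 3))
  expect_false(m$degenerate)
})

test_that("coverage by identity bins and counts bases correctly", {
  ref <- ann(start = 1, end = 1000)
  ref$divergence <- 30 # identity 70 -> bin [70, 75)
  pred <- ann(start = 1, end = 850)
  cov <- coverage_by_identity(ref, pred)
  row <- cov[cov$bin_lo == 70, ]
  expect_equal(row$ref_bases, 1000)
  expect_equal(row$coverage, 0.85)
  expect_equal(sum(cov$ref_bases), 1000)

  # prediction identical to reference: full coverage in occupied bins
  cov1 <- coverage_by_identity(ref, ref)
  expect_equal(cov1$coverage[cov1$bin_lo == 70], 1)
  # empty prediction: zero coverage
  cov0 <- coverage_by_identity(ref, ref[0, ])
  expect_equal(cov0$coverage[cov0$bin_lo == 70], 0)
  # top bin closed: identity exactly 100 lands in [95, 100]
  ref100 <- ann(start = 1, end = 10)
  ref100$divergence <- 0
  cov100 <- coverage_by_identity(ref100, ref100)
  expect_equal(cov100$ref_bases[cov100$bin_lo == 95], 10)

  refbad <- ann(start = 1, end = 10)
  expect_error(coverage_by_identity(refbad, pred),
               class = "tebench_input_error")
})

test_that("landscape histograms partition each family's bases", {
  gt <- tibble::tibble(seqid = "chr", start = c(1, 101, 301), end = c(100, 200, 400),
                       family = c("A", "A", "B"), divergence = c(5.2, 5.4, 12.1))
  ls <- divergence_landscape(gt)
  expect_equal(ls$bases[ls$family == "A" & ls$bin_lo == 5], 200)
  expect_equal(ls$bases[ls$family == "B" & ls$bin_lo == 12], 100)
  expect_equal(sum(ls$bases[ls$family == "A"]), 200)
  # disjoint divergence ranges give histograms with disjoint support
  expect_length(intersect(ls$bin_lo[ls$family == "A"],
                          ls$bin_lo[ls$family == "B"]), 0)
})

test_that("simulated landscape support is bounded by the divergence target", {
  cfg <- tiny_config(seed = 41, copies = 10, target_divergence = 0.3)
  sim <- simulate_genome(cfg)
  ls <- divergence_landscape(sim$ground_truth)
  expect_true(all(ls$bin_lo <= 30)) # no occupied bin above the 30% cap
  expect_true(all(sim$ground_truth$divergence <= 30))
})

test_that("track table labels segments in coordinate order", {
  sl <- c(chr = 100)
  ref <- ann(start = 1, end = 50)
  pred <- ann(start = 26, end = 75)
  tr <- track_table(ref, list(tool = pred), list(seqid = "chr", start = 1, end = 100), sl)
  expect_equal(tr$class, c("FN", "TP", "FP"))
  expect_equal(tr$start, c(1, 26, 51))
  expect_equal(tr$end, c(25, 50, 75))

  same <- track_table(ref, list(t = ref), list(seqid = "chr", start = 1, end = 100), sl)
  expect_true(all(same$class == "TP"))
  none <- track_table(ref, list(t = ref[0, ]), list(seqid = "chr", start = 1, end = 100), sl)
  expect_true(all(none$class == "FN"))
  expect_error(track_table(ref, list(t = pred),
                           list(seqid = "chr", start = 1, end = 101), sl),
               class = "tebench_input_error")
})

test_that("region masking subtracts and splits intervals", {
  a <- ann(start = 1, end = 100)
  mask <- ann(start = 41, end = 60)
  out <- exclude_regions(a, mask)
  expect_equal(out$start, c(1, 61))
  expect_equal(out$end, c(40, 100))
  # empty mask: unchanged
  expect_equal(exclude_regions(a, mask[0, ])[, c("start", "end")],
               tibble::tibble(start = 1L, end = 100L))
  # full containment: empty result
  expect_equal(nrow(exclude_regions(ann(start = 45, end = 55), mask)), 0)
  # covered-base arithmetic holds on random fixtures
  set.seed(55)
  for (i in 1:10) {
    x <- random_annotation(3000, 15)
    m <- random_annotation(3000, 10)
    got <- sum(coverage_vector(exclude_regions(x, m), "chr", 3000))
    xv <- coverage_vector(x, "chr", 3000)
    mv <- coverage_vector(m, "chr", 3000)
    expect_equal(got, sum(xv & !mv))
  }
})

test_that("masking before scoring removes masked bases from every count", {
  sl <- c(chr = 100)
  ref <- ann(start = 1, end = 50)
  pred <- ann(start = 26, end = 75)
  cm <- confusion_matrix(ref, pred, sl, mask = ann(start = 1, end = 25))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 75)
  expect_equal(cm$fn, 0) # the FN quarter was masked out
})
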
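# tebench

Benchmarking de novo transposable-element (TE) detection needs a genome
where the truth is known exactly. `tebench` builds one — and then scores
any repeat annotation against it at single-base resolution.

It is aimed at people who run or develop repeat finders (k-mer counters
such as Red/P-Clouds/phRAIDER, model builders such as
RepeatScout/RepeatModeler/REPET) and want an honest, tool-agnostic
yardstick:

* **Simulate** — plant mutated, 5'-truncated and nested copies of TE
  consensus sequences into a random base sequence of configurable length
  and GC content. Output: FASTA genome + exact GFF3 ground truth + run
  summary, byte-reproducible from one seed.
* **Evaluate** — merge annotations to covered base sets and classify
  every base of the genome as TP / FP / FN / TN, then derive the
  Matthews correlation coefficient

  ```
  MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
  ```

  together with sensitivity, specificity, precision and F1. MCC uses all
  four cells of the confusion matrix, so it behaves on the heavily
  imbalanced repeat-vs-background problem: 1 = perfect, 0 = no better
  than random guessing, −1 = fully wrong. Coverage-by-identity tables,
  per-family divergence landscapes and TP/FP/FN track tables (with
  `autoplot()` methods) come from the same machinery.
* **Audit models** — align de novo consensus models back to the
  reference families (local alignment, both orientations, iterative so
  duplicated content yields multiple hits) and classify each model as
  `perfect` / `good` / `present` / `not_found`, flagging homodimeric,
  chimeric, fragmentary and redundant models, plus a per-family
  recovery report.

## Worked example

```r
library(tebench)
library(dplyr)

lib <- make_fixture_library(3, length_range = c(300, 1500), seed = 1)
fams <- bind_rows(lapply(names(lib), function(nm) {
  family_spec(nm, lib[[nm]], copies = 8, target_divergence = 0.12,
              fragment_fraction = 0.25,
              nesting_fraction = if (nm == "synthfam03") 0.25 else 0)
}))
sim <- simulate_genome(simulation_config(fams, base_length = 50000,
                                         seed = 42))
glance(sim)
#> # A tibble: 1 × 7
#>   length base_length te_bases te_percent gc_percent n_copies n_families
#>    <int>       <int>    <dbl>      <dbl>      <dbl>    <int>      <int>
#> 1  68778       50000    18778       27.3       44.3       24          3
```

The 50 kb base grew to 68,778 bp by absorbing 24 TE copies (18,778
bases, 27.3% of the genome), every one recorded in
`sim$ground_truth` with family, strand, realized divergence, truncation
and nesting. Now score a deliberately sloppy "detector" — the truth
shifted right by 150 bp:

```r
sl <- setNames(nchar(sim$sequence), sim$seqid)
truth <- merge_intervals(sim$ground_truth)
pred <- mutate(sim$ground_truth, start = pmin(start + 150, sl),
               end = pmin(end + 150, sl))
cm <- confusion_matrix(truth, merge_intervals(pred), sl)
cm
#> <te_confusion>  TP: 15625  FP: 3153  FN: 3153  TN: 46847
#>   MCC: 0.7690
```

A 150 bp offset on every call costs this detector a quarter of its MCC:
3,153 TE bases missed and the same number hallucinated, for sensitivity
and precision of 0.832 each (`glance(cm)` gives the full metric row).
`coverage_by_identity()`, `divergence_landscape()` and `track_table()`
break the same comparison down by copy identity, family and position.

A command-line umbrella, `exec/te-sim-eval`, exposes the same pipeline
(`simulate`, `evaluate`, `assess-models`, `make-fixtures`, `out2gff`)
for shell use; RepeatMasker `.out` files are accepted on the prediction
side via the converter.

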
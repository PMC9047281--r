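---
title: "Simulating and scoring transposable-element annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring transposable-element annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tebench)
library(dplyr)
```

## The problem

De novo repeat finders disagree wildly, and on real genomes there is no
exact truth to score them against: curated annotations are themselves the
product of other software. `tebench` takes the complementary route — build
a genome where the truth is known by construction, then score any
predicted annotation against it at single-base resolution.

The package has three computational layers:

1. **Simulator** — plants mutated, truncated and nested copies of
   consensus sequences into a random background, emitting FASTA plus an
   exact GFF3 ground truth.
2. **Evaluator** — reduces any two annotations to covered base sets and
   classifies every base as TP/FP/FN/TN, from which the Matthews
   correlation coefficient (MCC) and companion metrics follow; it also
   produces coverage-by-identity tables, repeat landscapes and track
   tables for plotting.
3. **Model audit** — aligns de novo consensus models back to the
   reference families and classifies each model as perfect, good,
   present or not found, flagging homodimeric and chimeric pathologies.

## The simulation model and its assumptions

The base sequence is i.i.d. random with configurable GC: it contains no
repeats by construction, so every repeated structure in the output is a
planted TE. This is deliberately idealised — real intergenic DNA carries
tandem repeats, segmental duplications and compositional heterogeneity
(isochores), none of which are modelled. A detector's false-positive rate
measured here is therefore a lower bound on what real sequence would
provoke; conversely a tool that fails here fails for reasons intrinsic to
its algorithm, not to background complexity.

### Mutation model

Each copy receives `round(target_divergence * L)` mutation events,
apportioned among substitutions, insertions and deletions by
`mutation_weights` (default 0.80/0.10/0.10 — interspersed-repeat decay is
substitution-dominated) at distinct anchor positions of the consensus.
Indel lengths are geometric with mean `indel_mean_length` (default 3 bp;
short indels dominate neutral decay). Every event consumes budget equal
to its edit cost; indels are trimmed and events dropped once the budget
is spent, so the recorded divergence — the applied edit cost divided by
consensus length — never exceeds the target. Two numerical subtleties:

* `round()` can overshoot the ceiling by half an event on unlucky
  lengths; the budget then falls back to `floor(target * L)` so the cap
  is strict.
* The edit cost is an upper bound on the true alignment distance: when
  events are dense (near the 30% cap) independently drawn events
  interact and the optimal alignment is slightly cheaper than the event
  script. Divergence audits in the tests therefore use an independent
  dynamic-programming distance (`utils::adist`) and assert the one-sided
  cap, plus exact equality in the sparse regime where events cannot
  interact.

Consensus `N` bases pass through mutation untouched.

### Truncation, strand and nesting

A `fragment_fraction` share of each family's copies loses
`u ~ Uniform(0, max_truncation]` of its length from the 5' end — the
decay mode typical of LINE-like retrotransposition. Truncation happens
before reverse-complementing, so minus-strand copies (strand is uniform)
lose their own 5' end. A `nesting_fraction` share of copies is inserted
strictly inside a previously placed copy of a *different* family,
splitting the host's annotation into flanking intervals under one copy
identifier. Nesting depth is 1: a nested copy never hosts another. Real
genomes do show deeper nesting ladders; depth 1 matches the pairwise
nestings this framework is designed to probe (chimeric model detection)
while keeping ground-truth intervals trivially disjoint.

Insertions expand the sequence (never overwrite), with offsets drawn
without replacement in the base coordinate frame, so

* final length = base length + total post-truncation copy length, and
* ground-truth intervals tile exactly the inserted bases —

two invariants asserted exactly in the test suite. All randomness flows
from one master seed through stage-derived streams (`derive_seed`), so
any stage is replayable alone and whole runs are byte-identical.

### The packaged benchmark composition

`simulated_dataset_config()` reproduces the benchmark's simulated-genome
recipe at a configurable scale (default 1/10): a base sequence at 42% GC
(human-like) carrying 1.5× its mass of TE sequence — 60% of the emitted
genome — from 20 synthetic families with lengths log-spaced 311 bp to
18.5 kb (SINE to Polinton). Where the recipe leaves values open we fixed
them once at field-plausible levels: 10% of copies truncated (by up to
30%), 5% nested, and per-family divergence targets spread 5–30% with
most families in the 5–10% band so the bulk of copies sits 90–95%
identical to consensus. Copy counts give each family an equal share of
the TE mass.

## Scoring model

Both annotations are first reduced to covered base sets:
`merge_intervals()` joins overlapping, contained and bookended-adjacent
records (`max_gap = 0` by default; "adjacent" means a gap of zero
intervening bases). Scoring is repeat-vs-non-repeat by position — strand
and family labels are ignored, since the question is *detection*, not
classification. Per base: in both sets TP, prediction-only FP,
reference-only FN, neither TN; counts are summed over sequences and

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

MCC uses all four cells, so it stays honest on imbalanced genomes where
accuracy or F1 mislead. When a marginal is zero the quotient is
undefined; we return 0 with a `degenerate` flag (continuity convention).
Tandem-repeat masks (e.g. from Tandem Repeats Finder) can be supplied to
`confusion_matrix(mask=)`; masked bases are removed from both sets *and*
from the genome length, i.e. excluded rather than counted as TN.

`coverage_by_identity()` bins reference copies by identity
(= 100 − divergence, closed-left 5% bins, top bin closed) and reports
the detected fraction of reference bases per bin — the standard picture
of detection decaying with divergence. `divergence_landscape()` gives
the per-family histogram of annotated bases by divergence, and
`track_table()` exports TP/FP/FN segments per tool for region plots. All
three have `autoplot()` methods.

The interval-algebra implementation (IRanges reductions) is checked,
fixture by random fixture, against a literal per-base boolean-vector
oracle in the test suite; self-evaluation of simulator ground truth must
give FP = FN = 0, MCC = 1.

## Model audit

`align_models()` maps each de novo consensus model to each reference
family by local (Smith–Waterman) alignment in both orientations,
iteratively masking the matched model span so duplicated content yields
multiple hits. Hits shorter than 50 bp or below 60% identity are
discarded (configurable; the floor mirrors the simulator's divergence
range). Tabular 12-column alignment output from an external aligner can
be substituted via `read_blast_hits()`.

`classify_models()` scores each model against its best family:
*perfect* needs a single family, ≥95% identity and ≥95% reference
coverage in one collinear chain (hits in consistent order with ≤10%
mutual overlap — local aligners fragment long matches, so chaining
before coverage is essential); *good* keeps the identity bar with 50–95%
coverage; *present* is any qualifying hit below that; *not found* is
none. Flags capture the observed failure modes: *homodimer* (disjoint
model spans over one reference span — a duplicated consensus),
*chimera* (qualifying hits to ≥2 families, the signature of nested
insertions leaking into a model), *fragment* (<50% coverage),
*redundant* (several models share a best family). `family_report()`
inverts the view: models per family and families missed outright.

## What passing tests do and do not show

The simulator's i.i.d. background and literal-consensus families make
every score exact but optimistic: no low-complexity sequence, no
subfamily structure, no gene content, divergence applied in one step
rather than along an insertion-age continuum. Results transfer to real
genomes as *relative* tool comparisons, not absolute performance
promises.

## Problem sizes and numerical choices

The shipped checks run at desk scale, chosen as the package's own
defaults: the composition check at 1/10 of the full recipe (4 Mb base +
~6 Mb TE, ~60% TE fraction within one point), GC at 1 Mb against 3
binomial standard deviations, the divergence-cap audit on 1,000 copies
across 5 families with per-copy DP re-measurement, oracle equivalence on
100 random fixtures up to 100 kb, and 200-replicate random-prediction
MCC means. Degenerate inputs are defined, not special-cased: zero target
divergence returns the copy verbatim, `fraction = 0` truncation is the
identity, empty predictions give TP = FP = 0, and empty masks are
no-ops. Ties in placement cannot occur (offsets are drawn without
replacement); equal nested insertion points splice in copy-identifier
order.

## Worked example

```{r example}
lib <- make_fixture_library(3, length_range = c(300, 1500), seed = 1)
fams <- bind_rows(lapply(names(lib), function(nm) {
  family_spec(nm, lib[[nm]], copies = 8, target_divergence = 0.12,
              fragment_fraction = 0.25,
              nesting_fraction = if (nm == "synthfam03") 0.25 else 0)
}))
sim <- simulate_genome(simulation_config(fams, base_length = 50000,
                                         seed = 42))
glance(sim)

sl <- setNames(nchar(sim$sequence), sim$seqid)
truth <- merge_intervals(sim$ground_truth)

## a deliberately sloppy "detector": truth shifted right by 150 bp
pred <- mutate(sim$ground_truth, start = pmin(start + 150, sl),
               end = pmin(end + 150, sl))
cm <- confusion_matrix(truth, merge_intervals(pred), sl)
cm
glance(cm)
```

```{r landscape, fig.width = 6, fig.height = 3}
autoplot(divergence_landscape(sim$ground_truth))
```

## Known limitations

* No tandem/simple repeats or segmental duplications are simulated;
  masks for them are consumed, never produced.
* Output is an assembled sequence; no read-level simulation.
* Family-level *classification* accuracy is out of scope — scoring is
  detection-only, and the audit module evaluates consensus recovery, not
  genome-wide naming.
* The internal aligner reports one optimal local hit per masking
  iteration; alignments of models against very long references inherit
  quadratic cost, so audits are meant for consensus-scale sequences
  (≲ 20 kb), not chromosomes.
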
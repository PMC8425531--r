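---
title: "Mutation histories of tandem repeat regions: model, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation histories of tandem repeat regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatsig)
```

## The model

A tandem repeat (microsatellite) is a genomic region in which a short
pattern of at most 10 nucleotides repeats consecutively.  Two kinds of
events shape such a region over time: **tandem duplications**, in which one
existing copy of the pattern (a *block*) is duplicated and the copy
inserted immediately to its right, and **point mutations** — substitutions,
insertions and deletions of single nucleotides.  Crucially, a point
mutation that strikes a block *before* that block is duplicated propagates
into all later copies, while a mutation arriving after the last duplication
marks a single copy.  The ordering of events therefore leaves a
reconstructible trace in the present-day sequence.

`repeatsig` summarises each region by its **mutation index** `(m, d)`:

* `d`, the **copy number**, is the number of pattern-length blocks that
  tile the region;
* `m`, the **error number**, is the smallest total count of substitutions,
  insertions and deletions over all single-block duplication histories that
  generate the observed region from some root of the pattern length.

Parsimony is the model-selection rule: among all histories that explain a
region, the one with the fewest point mutations is preferred.  A region
that is a perfect `d`-fold repeat of its pattern has `m = 0`.

Concatenating `(m, d)` over all repeat regions of a sample's contigs — a
vector twice the region count wide — gives the sample's **mutation
profile**, the feature vector used for classification.

## Pipeline stages

### Detection

`detect_repeats()` is a self-contained short-tandem-repeat detector: for
every candidate period `p = 1..10` it marks positions that agree with the
sequence `p` characters earlier, seeds candidates at runs of `p` exact
agreements (two adjacent exact copies), extends them under X-drop scoring
(`match_weight` +1, `mismatch_weight` −2, `xdrop` 4), trims to a whole
number of copies at the offset maximising periodic agreement, and takes the
column-wise majority over blocks as the consensus pattern, reduced to its
primitive period and reported in canonical (lexicographically smallest)
rotation.  Because an indel shifts the phase of the fixed-period agreement
vector, one mutated region appears as two adjacent candidates; candidates
whose canonical patterns agree within one edit and whose gap is at most the
period plus four are re-joined.  Overlaps are resolved by the periodicity
alignment score (then length, then smaller period, then leftmost), and a
region must be at least 7 nt long and at least two full copies — the role a
minimum alignment score plays in other detectors, suppressing the chance
`AA`/`ACA` periodicities that occur everywhere in random sequence.  Regions
are reported in 0-based half-open coordinates, at most 1000 nt, copy number
at most 100.

```{r}
detect_repeats("ATGACGTGAGTGAGTGAGT")
```

`read_trf_table()` ingests Tandem Repeat Finder `.dat` tables into the same
catalog shape (converting their 1-based inclusive coordinates and dropping
records outside the size limits), so externally produced repeat calls can
substitute for the built-in detector.

### History estimation

`partition_blocks()` cuts a region into consecutive blocks scored by
Levenshtein distance against one rotation of the pattern, minimising total
distance, then the number of non-identical adjacent block pairs, then the
deviation of block lengths from the pattern length — equivalent to cutting
the optimal wraparound alignment against cyclic pattern repetitions at
period boundaries.  The block count is `d`.

`estimate_index()` reconstructs the cheapest history it can find in
polynomial time.  Runs of identical adjacent blocks collapse at no cost
(they un-do exact duplications); the collapsed block list is then reduced
to a single survivor by an interval dynamic program that is exact over all
ordered duplication trees whose internal contents are lifted from the
blocks, with one refinement: the final merge may root at *any* string of
the pattern length, found exactly by a three-way alignment (two surviving
lineages may both derive from a root seen in neither, e.g. one copy gained
an insertion and another a deletion before each was duplicated).  Because
the phase of the tiling is not known in advance, the reduction is taken
over every rotation of the pattern, both partition tie-break orders, and a
small set of alternative tiling anchors (the region's prefixes and
suffixes of length `p±1` and the modal partition block), which recover
histories whose effective repeat unit is an early-mutated variant of the
pattern.  Every candidate corresponds to a concrete feasible history, so
the result is always an upper bound on the true minimum; `d` is always the
pattern-anchored block count.

`estimate_index_exact()` computes the true minimum by iterative deepening
over the mutation budget, enumerating intermediate block contents from
edit-distance balls with memoisation.  It is exponential in `m` and
guarded to regions of at most 24 nt with patterns of at most 4 nt; within
the guard it is the package's reference oracle.  On 1000 simulated guarded
regions the polynomial estimator matches the exact minimum on more than
99% of instances and never undercuts it (see `tests/testthat/`).

```{r}
estimate_index_exact("ACGTACGTACATAGAT", 4)
estimate_index(list(region_sequence = "ACGTACGTACATAGAT", pattern = "ACGT"))
```

### Profile alignment

Repeat regions present in one sample may be absent in another, and
patterns of homologous regions may differ slightly, so profiles must be
reconciled positionally before learning.  `align_profiles()` computes a
global monotone alignment of a sample's profile against a reference
profile, minimising the sum of **normalized edit distances** between paired
patterns — Levenshtein distance divided by the mean pattern length — plus a
fixed **missing-pattern cost of 0.4** for every unpaired entry on either
side.  Two patterns at normalized distance below 0.4 are thereby
effectively treated as equal, while more distant pairs are better left
unmatched.  Cost ties prefer fewer gaps, then a deterministic traceback
that places gaps leftmost.  Entries are matched within the same sequence
id; query-only regions (absent from the reference) are dropped;
reference regions left unmatched are filled with `(0, 0)`, giving every
sample an identical feature layout (`build_matrix()`).

```{r}
q <- tibble::tibble(sample_id = "patient1", seq_id = "s",
                    start = c(0L, 100L), end = c(7L, 102L),
                    pattern = c("A", "CG"), m = c(0L, 1L), d = c(7L, 4L))
r <- tibble::tibble(sample_id = "reference", seq_id = "s",
                    start = c(0L, 100L, 200L), end = c(8L, 104L, 202L),
                    pattern = c("A", "CGTA", "CG"), m = c(0L, 0L, 1L),
                    d = c(8L, 3L, 3L))
align_profiles(q, r)
attr(align_profiles(q, r), "cost")
```

### Classification

`train_pairwise()` and `train_multiclass()` implement a two-step
gradient-boosted scheme on the aligned matrix.  Step one fits depth-2
boosted trees under stratified 4-fold cross-validation and ranks features
by fold-averaged total split gain; the top 30 features are retained.  Step
two fits depth-1 boosted trees per fold on the selected features — a binary
classifier for every unordered class pair (K classes give K(K−1)/2
reports), or a soft-probability multiclass model.  Validation folds yield
AUC (Mann–Whitney rank statistic), accuracy, sensitivity and specificity at
a 0.5 probability threshold, ROC points, and out-of-fold class probability
profiles; `report_metrics()` aggregates means ± standard deviations and
square all-pairs seriation matrices.

Feature selection is run once per classifier on that classifier's full
cohort (with fold-averaged importances), not re-nested inside each fold.
This mirrors the two-step structure but lets selection see the validation
folds, so null-cohort AUC sits above 0.5.  The null-calibration check
therefore compares against a label-permutation distribution — 200
retrainings under shuffled labels, which share the leak — rather than a
fixed 0.5 band.

## The synthetic cohort generator

`generate_cohort()` builds a labelled cohort with complete ground truth,
emulating the structure of a blood-derived whole-exome study: several
hundred samples per class for around eleven classes, with one "signature"
class whose mutation activity differs in a planted subset of regions.  For
each region a primitive random pattern (1–10 nt) is drawn; for each sample
and region a duplication count `1 + Poisson(lambda_d − 1)` (at least two
copies) and mutation count `Poisson(lambda_m)` are drawn and played through
`simulate_history()`, which interleaves duplications and point mutations
uniformly at random so that mutations may or may not propagate — the two
qualitative history types the estimator must distinguish.  The effect
class's lambdas are shifted additively (`m_shift`, `d_shift`) in the signal
regions only.  Default base rates are `lambda_d = 5` (about six copies,
typical of short microsatellites) and `lambda_m = 1` — one expected point
mutation per region, enough that histories are informative but most
regions stay close to their pattern.  Regions drop out of a sample with
probability 0.1, and with probability 0.05 a sample's region is seeded
from a one-edit pattern variant, exercising the alignment's near-match
logic.

Regions are joined by random spacers (30–50 nt, drawn from a pool
rejection-sampled until the detector finds no repeat in them) whose
junctions are verified to break the flanking region's periodicity for at
least four positions, so planted boundaries are unambiguous and detector
recall is measurable.  Deletions that would empty a length-1 block are
redirected to an eligible position (or re-drawn as substitutions when all
blocks have length 1), keeping the witness mutation count equal to the
requested event count.  The zero-mutation ancestor sequence — every region
as a perfect repeat at the expected copy number — serves as the cohort's
reference genome; the reference profile is computed from it by the same
detect-and-index path as every sample.

What the generator does *not* emulate: read-level sequencing (coverage,
base-calling error, alignment artifacts), interspersed repeats, linkage
between regions, and any real biological mutation process — the
Poisson/additive-shift law is a minimal stand-in chosen for
interpretability, not a claim of biological fidelity.  Tests passing on
these cohorts validate the pipeline's internal consistency, not its
performance on real exomes.

## Validation strategy and what the checks mean

* **Replay closure** — every simulated history re-executes from its root to
  exactly the emitted sequence, so ground truth is internally consistent.
* **Detection recall** — on zero-mutation cohorts (perfect repeats with at
  least 3 copies, patterns of at least 2 nt, length at least 7) at least
  95% of planted regions are recovered with exact boundaries.
* **Witness bound** — the simulated history is a feasible history, so for
  every planted region recovered by detection at its true period, the
  estimated `m` must not exceed the simulated mutation count.  The
  restriction to true-period recoveries keeps the comparison
  model-consistent: when detection reports a different period (for
  example a heavily mutated region read as a homopolymer), the planted
  history is not a history of the reported model and the bound's premise
  fails.  The recovered fraction is reported alongside.
* **Oracle equivalence** — on guarded instances the estimator is compared
  with the exact search; the equality rate is the published diagnostic of
  the estimation heuristics.
* **Null calibration and planted recovery** — zero-shift cohorts score
  inside their label-permutation interval, and a cohort with `m_shift = 3`
  in 10 of 100 regions (100 samples per class) yields mean pairwise AUC of
  at least 0.8 for the effect class, non-decreasing across
  `m_shift ∈ {0, 1, 3}`.

The problem sizes used in the shipped checks — cohorts of 40–300 samples
with 15–100 regions, 1000 oracle instances, 200 permutations — were chosen
as the smallest at which the statistics above are stable; they run on a
single CPU in a few minutes.

## Numerical and design choices

* Edit (Levenshtein) distance is used throughout, not Hamming distance:
  indels change block lengths and Hamming comparisons would mis-score
  phase-shifted blocks.
* `d` is the integer block count of the partition; the detector's
  fractional `copy_count` (region length / period) is kept in the catalog
  for reference.
* Pattern identity is defined up to rotation; the canonical form is the
  lexicographically smallest rotation and all cross-sample comparisons use
  it.
* The boosting configuration (100 rounds, learning rate 0.3, no
  subsampling, no reweighting of unbalanced classes) is fixed in
  `classifier_config()` and recorded in every pipeline manifest; the
  operating threshold for sensitivity/specificity is 0.5.
* Class probabilities come from single-precision boosting, so "rows sum
  to one" holds to about `1e-6`, not machine double precision.
* Degenerate inputs: empty sequences give empty catalogs; regions shorter
  than their pattern are rejected; a profile with no matching regions
  aligns to an all-gap row of `(0, 0)` and can still be scored.
* Alignment tie-breaks (fewer gaps, then leftmost placement) and the
  estimator's deletion tie-break (drop the right member) are fixed for
  determinism; cohort generation, fold assignment and training are exact
  functions of their seeds.

## Known limitations

* The polynomial estimator is an upper bound; on about 1% of dense
  multi-variant histories it exceeds the true minimum (and occasionally a
  simulated witness count) by one.  The exact search removes this but is
  limited to small regions.
* The detector's fixed-phase scan can truncate regions whose ends are
  heavily mutated, biasing `m` downward for extreme mutation loads; the
  candidate-merging step recovers single interior indels but not dense
  clusters near boundaries.
* Pairwise AUCs inherit the selection leak discussed above; they are
  comparable across pairs and cohorts trained identically, but are not
  unbiased estimates of generalisation performance.
* Everything here is validated on synthetic cohorts only; applying the
  pipeline to real exome data would additionally require read-level
  processing far outside this package's scope.
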
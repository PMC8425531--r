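# repeatsig

Mutation histories of short tandem repeat regions, and the class
signatures they carry.

## The problem

Short tandem repeats (microsatellites) evolve by two interleaved
processes: *tandem duplications*, which copy one repeat unit next to
itself, and *point mutations* (substitutions, insertions, deletions).  A
mutation that strikes a unit before it is duplicated propagates into all
later copies, so the present-day sequence of a repeat region retains a
trace of the *order* in which events happened.  `repeatsig` reconstructs,
for every repeat region of a sample, the most parsimonious single-block
duplication history and summarises it by the **mutation index**

&nbsp;&nbsp;&nbsp;&nbsp;(*m*, *d*),

where *d* is the copy number (the number of pattern-length blocks tiling
the region) and *m* is the error number — the minimal total count of
substitutions, insertions and deletions over all histories that generate
the observed region.  For example, the region `ACGTACGTACATAGAT`
(pattern length 4) is explained by a history with two point mutations,
so (*m*, *d*) = (2, 4): cheaper than mutating the third and fourth copy
independently, because one of the two mutations propagated through a
later duplication.

Stacked over all repeat regions of a genome, these indices form a
sample's **mutation profile** — an intrinsic, per-individual record of
mutation activity that needs no comparison across genomes.  Profiles are
aligned to a reference profile by a dynamic program on the normalized
edit distance between repeat patterns (unmatched entries cost 0.4) so
that every sample yields a fixed-width feature vector, and sample
classes are then discriminated by a two-step gradient-boosted scheme:
depth-2 boosted trees select the 30 most informative features under
4-fold cross-validation, and depth-1 boosted classifiers — one per class
pair, plus a soft-probability multiclass model — quantify how separable
the classes' mutation histories are (AUC, accuracy, sensitivity,
specificity per fold).

The package is aimed at method developers: it ships a synthetic cohort
generator with complete ground-truth histories, so every stage —
detection, history estimation, alignment, classification — is testable
end to end without access to controlled human sequencing data.

## Worked example

```r
library(repeatsig)

# a cohort of 3 classes x 40 samples, 40 repeat regions; class01 carries
# extra mutation and duplication activity in regions 1-8
spec <- cohort_spec(n_classes = 3, samples_per_class = c(40, 40, 40),
                    n_regions = 40, signal_regions = 1:8, effect_class = 1,
                    m_shift = 3, d_shift = 2, seed = 42)
cohort <- generate_cohort(spec)

# detect repeats and estimate (m, d) for every sample and the reference
profiles <- dplyr::bind_rows(lapply(names(cohort$sequences), function(sid)
  mutation_profile(detect_repeats(cohort$sequences[[sid]], seq_id = sid), sid)))
reference <- mutation_profile(
  detect_repeats(cohort$reference$sequence, seq_id = "ref"), "reference")

# align against the reference and train all pairwise classifiers
mat <- build_matrix(profiles, reference, labels = cohort$labels)
pw  <- train_pairwise(mat, config = classifier_config(seed = 42))
report_metrics(pw)$summary[, c("class_a", "class_b", "auc_mean", "auc_sd")]
#> # A tibble: 3 × 4
#>   class_a class_b auc_mean auc_sd
#>   <chr>   <chr>      <dbl>  <dbl>
#> 1 class01 class02    0.605 0.09
#> 2 class01 class03    0.76  0.112
#> 3 class02 class03    0.692 0.129
```

The planted class separates from the others; the per-fold spread (and the
fact that feature selection sees the whole pair cohort, which lifts even
null pairs above 0.5 — see the vignette) is why conclusions should rest on
permutation baselines, not the raw numbers.  At larger cohort sizes the
separation is unambiguous: with 100 samples per class the effect class
reaches mean pairwise AUC around 0.9 while the permutation baseline stays
flat (see `tests/testthat/test-acceptance.R`).

Single regions can be inspected directly:

```r
detect_repeats("ATGACGTGAGTGAGTGAGT")
#> # A tibble: 1 × 8
#>   seq_id start   end pattern period copy_count score region_sequence
#>   <chr>  <int> <int> <chr>    <int>      <dbl> <dbl> <chr>
#> 1 seq        5    17 AGTG         4          3     8 GTGAGTGAGTGA

estimate_index_exact("ACGTACGTACATAGAT", 4)
#> $m
#> [1] 2
#> $d
#> [1] 4
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/repeatsig.R` (subcommands `simulate`, `detect`, `index`,
`align`, `classify`, `run`, `score`), and `run_pipeline()` orchestrates
all stages with a checksum-based manifest so finished stages are skipped
on re-run.

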
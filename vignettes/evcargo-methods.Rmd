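---
title: "Methods: small RNA cargo and single-EV heterogeneity analysis"
author: "evcargo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA cargo and single-EV heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcargo)
```

# Scope

`evcargo` implements the computational arm of a study design in which
androgen-receptor-positive prostate cancer cells (LNCaP) are grown with or
without dihydrotestosterone (DHT) and both the cells and the small
extracellular vesicles (S-EVs) they secrete are profiled: (i) small RNA-seq
of the four pooled libraries (cells and S-EVs, each ± DHT) through adapter
trimming, tiered exact-match annotation, predominant-fragment calling,
reads-per-million (RPM) differential analysis and isomiR taxonomy; and
(ii) single-particle interferometry of vesicles captured on tetraspanin
antibody spots (CD9/CD63/CD81, plus CD41a for plasma and IgG isotype
controls), with per-combination background subtraction, 5-nm
size-frequency distributions and group testing.  Because no raw data from
such a study are available to a package, a synthetic-data generator with
planted ground truth is a first-class module: every downstream stage is
tested by parameter recovery against what was planted.

# The sequencing pipeline and its assumptions

## Adapter trimming

Reads are 50-nt single-end: an insert (16–30 nt of biology), the 3'
sequencing adapter, and downstream bases.  `trim_read()`/`trim_set()`
re-implement 3'-adapter trimming with the protocol's parameters: maximum
error rate 0.1, minimum overlap 3 nt, minimum retained length 15 nt,
untrimmed reads discarded.  Two deliberate simplifications, both
documented properties rather than incidental behaviour:

* **Hamming-only matching.** Errors are substitutions; indels are not
  modelled.  Small-RNA adapter hits are short and near-exact, and the
  substitution-only model admits an *exact* exhaustive-search oracle,
  against which the vectorised implementation is tested on 10^4 random
  reads.
* **Leftmost minimum-error occurrence.** Among qualifying occurrences
  (full, or 3'-terminal with length ≥ min_overlap) the fewest-error one
  wins, ties to the earliest adapter start.  'N' never matches.

The default adapter is the Illumina TruSeq small-RNA 3' adapter motif;
the protocol names the kit but not the sequence, so it is configurable.

## Tiered exact-match annotation

The original analysis mapped reads with a short-read aligner run
end-to-end with score floor zero ("--end-to-end --score-min C,0").  Under
a zero floor no mismatch or gap penalty is admissible, so a reported
alignment is exactly a verbatim substring match; seed-mismatch and
padding parameters are irrelevant at that floor.  `run_cascade()`
therefore replaces the aligner with an exact-substring index
(`build_index()`), which is tested against a naive enumeration oracle.
Tiers are tried in order — rRNA (exclusion), curated ncRNA classes, piRNA
— and the first tier with a hit claims the read; reads surviving all
tiers are reported `unmapped`.  Genome-level mapping of leftovers is out
of scope.  Matching is sense-strand only (stranded libraries);
within-tier multimapping is resolved deterministically (smallest ref_id,
then smallest offset) with the hit count kept in `multimap_count` so the
choice is auditable.  The tie-break is a declared convention: the
original study does not state one.

## Predominant-fragment calling

`call_fragments()` identifies the dominant processed species per
reference from read-termini consensus, in the spirit of FlaiMapper-style
calling: 5' peaks are strict local maxima of the read-start profile
within ±w (default 2 nt) with at least `min_support` (default 2) reads;
each peak's 3' end is the modal end among reads starting within ±w of the
peak (ties to the smallest end); candidate fragments whose both termini
fall within ±w of a better-supported fragment are merged into it and the
survivor is flagged for curation rather than silently dropped.  The cited
tool's internals are not restated in the protocol, so these defaults are
this package's specification, chosen to tolerate the ubiquitous ±1-nt
end variation while still separating 5p from 3p arms.  Calling is
performed on reads pooled over the four libraries (whether the original
analysis pooled is unstated); counting is per library, with a read
supporting the unique fragment whose termini both lie within the
assignment tolerance (default 2 nt), nearest-termini ruling on overlap
and residual reads counted separately.  One consequence worth noting:
distinct isomiRs of one arm are *not* deconvolved into separate fragments
— the dominant form is called and classified downstream, which mirrors
the original workflow.

## Quantification and differential calls

RPM scaling uses, per library, the reads assigned to any small-RNA tier
after rRNA exclusion as the denominator, so RPM columns sum to 10^6 over
all small-RNA features and libraries of very different composition (80%
small RNA in cells vs ~10% in S-EVs) remain comparable.  A feature is
included when it reaches 10 raw reads in at least one library.  The
protocol states this rule in two conflicting forms (at least 10 in *any*
library, vs excluded if below 10 in any library); the inclusive reading
is the default and `strict = TRUE` gives the conjunctive one.  The
differential rule is the protocol's pure fold-change criterion: linear
fold change `(rpm_b + c)/(rpm_a + c)` with `c = 1` RPM always added —
continuity at zero and exact antisymmetry under swapping conditions —
and a call at ≥ 4-fold in either direction.  Whether the original
analysis used a pseudocount is unstated; `c` is configurable and the
default is declared, not inferred.  No replicate-aware model is fitted:
the libraries are pools of three biological repeats, and the package
deliberately reproduces the fold-change-only design rather than adding a
dispersion model the data could not support.

## IsomiR taxonomy

Differentially expressed miRNA-precursor fragments (all fragments, with
`only_de = FALSE`) are compared against the canonical mature annotation
of their hairpin.  A fragment is attributed to the region of maximal
overlap (annotated arms and the opposite-arm region take precedence over
the loop, which takes precedence over flanks).  On an annotated arm the
signed offsets d5 (fragment start − canonical start) and d3 (fragment
end − canonical end) drive an exhaustive decision table: canonical
(0,0); shorter/longer 3' or 5' ends for one-sided offsets; shifts toward
the 3' or 5' direction when both offsets share a sign; shorter-at-both /
longer-at-both for opposite signs.  `longer_both` was never observed in
the motivating data and is reported separately, but the table is
exhaustive by construction (a property test covers all of
[-5,5] × [-5,5]).  Fragments on the unannotated arm are opposite-arm
products; for single-arm hairpins the opposite-arm region is the
annotated arm mirrored across the loop midpoint, since miRBase-style
single-arm entries give no second annotation.  Loop fragments are
stem-loops; flank fragments are trailers, restricted to the deposited
precursor's flanks (coordinates beyond the deposited hairpin are
unknowable).  The taxonomy summary reports counts, an isomiR subtotal
over the eight end-variant categories, and integer percentages of the
grand total.

# The synthetic-data generator

`make_reference_bundle()` builds a miRBase-like reference: hairpins of
120–140 nt with 18-nt flanks, arms of 20–23 nt and the remainder as
loop, one annotated mature arm in five precursors (always at least one)
to exercise opposite-arm logic, plus rRNA, tRNA, snoRNA (SNORD/SNORA),
scaRNA, snRNA, scRNA, piRNA and misc entries at class-typical lengths.
rRNA entries are 600–900 nt — shorter than real cytoplasmic rRNA, which
is irrelevant because contamination reads are windows on them.

`design_androgen_experiment()` plants features under the study
conditions; `design_recovery_benchmark()` is the power-adequate recovery
variant.  Shared machinery:

* **Class mixture.** Features follow the detected-species mixture of the
  motivating data (roughly half miRNA, then SNORD, piRNA, tRF, SNORA,
  and small scaRNA/snRNA/scRNA contributions), with planted
  opposite-arm, trailer and stem-loop products among the
  miRNA-precursor features.
* **Length regimes.** Cell-pool features are 22–23 nt and EV-pool
  features 18–28 nt, one jitter step inside the reported read-length
  supports (20–25 nt cells, 16–30 nt EVs), since independent ±1-nt
  termini jitter can change a length by up to 2 nt.  Noise and rRNA
  window lengths follow each library's regime so the per-library length
  histograms have exactly the reported support.
* **GC by biased feature selection.** Candidates are over-generated
  3-fold and pools are filled by sampling with Gaussian weights around
  GC targets of 45.5% (cell pool) and 54.5% (EV pool) — selection bias,
  not per-read rejection — reproducing the reported GC contrast
  (45–46% cellular vs ~53% EV libraries) in the small-RNA-assigned
  reads.
* **Mass-balanced differential planting.** Planted fold changes are
  ratios of within-library expected proportions.  Because proportions
  renormalise, unbalanced planting shrinks every realized contrast (an
  up-regulated feature deflates all others).  Responsive features are
  therefore planted as up/down pairs within one compartment pool, the
  down partner carrying weight w × fc: each pair holds the same read
  mass in both conditions, so realized proportions reproduce planted
  fold changes exactly in expectation.  Responsive features are planted
  in the well-expressed range (weights 2–5 against a lognormal(0, 0.6)
  background), as detectable androgen-responsive cargo is in real
  libraries.
* **Composition.** The study preset uses 80% small-RNA reads in cell
  libraries and 10% in EV libraries (with 5%/10% rRNA and the rest
  unmappable noise), matching the reported composition; the recovery
  benchmark uses 85% small RNA in all four libraries so that a 4-fold
  contrast is identifiable at 10^5 reads/library.  Small fractions of
  adapter-free reads and sub-15-nt inserts exercise the trimming
  filters; adapter-free reads are rejection-sampled so that no spurious
  3'-terminal occurrence qualifies.
* **Determinism.** Every generator is byte-identical for a fixed seed;
  read ids record the library and the truth feature (or noise class), so
  conservation can be asserted exactly.

What the generator does **not** emulate: sequencing errors and quality
variation (qualities are a constant Q30), non-templated 3' additions
(classification is by templated coordinates only), repeat-level
biological variance (each library is one pooled sample, as in the
motivating design), multimapping families of near-identical references,
and RNA-ligase sequence bias.  Passing recovery tests therefore
demonstrates correctness of the pipeline's logic under its stated
contract — exact matching, fold-change calls on planted truth — not
robustness to error-ridden or biased real libraries.

The recovery criterion counts a planted responsive feature as recalled
when it is called in at least one compartment contrast (cells or
S-EVs), mirroring how the motivating analysis reports androgen
responsiveness ("differentially expressed either in EVs or cells");
with planted folds drawn uniformly from [4, 8] and the call threshold
at exactly 4, a feature planted at the boundary is expected to sit
within sampling error of it, so single-contrast recall would be an
unfair test of the pipeline rather than of the design.

# The single-EV module

`simulate_particles()` draws, per subject and capture spot, a Poisson
particle count (with a lognormal per-subject scaling shared across that
subject's spots, sdlog 0.3), Normal diameters centred on the planted
modal 5-nm bin's midpoint (sd 4 nm) clipped to the instrument range
(30–250 nm), and independent Bernoulli channel positivity for the
CD9/CD63/PSMA detection channels.  IgG spots draw from a background-only
rate.  The patient preset uses the cohort sizes of the motivating study
(BPH n=10, LPCa n=11, AdvPCa n=15), 50-nm modes for CD63/CD81, 55-nm
modes for CD9, a CD9-capture excess in the advanced group and PSMA
positivity rising with stage; a treatment-arm preset covers the
FBS/CSS/DHT/ENZ culture design.

Analysis: `filter_size_window()` applies the 50–200 nm sizing window,
inclusive at both edges; `size_frequency()` bins at 5 nm, left-closed,
labelled by the lower edge (the reporting granularity of the motivating
figures), percentages summing to 100 exactly.  `count_subpopulations()`
computes, for each capture spot and each sign combination of the three
detection channels, `max(raw − IgG background, 0) × dilution`.
Subtracting per combination rather than on spot totals is a declared
refinement of the isotype-control normalisation (the protocol's wording
covers totals only); the eight combinations partition each spot's
particles before subtraction, which is asserted as an invariant.
`compare_groups()` uses the Kruskal–Wallis rank test with Dunn-style
pairwise z follow-ups (Holm-adjusted) for independent patient groups —
the post-hoc method is not named in the motivating work, so Dunn/Holm
is this package's declared choice — and ordinary one-way ANOVA with
Tukey comparisons for treatment arms.  Channel positivity thresholds
are assumed pre-computed by the instrument; the module consumes boolean
positivity, not raw intensities.

# Numerical and design choices

* Coordinates are 0-based half-open throughout (BED-style); `d5`/`d3`
  are signed integers in those coordinates.
* The opposite-arm mirror of [a, b) across a loop [l1, l2) is
  [l1+l2−b, l1+l2−a), clipped to the precursor.
* Degenerate inputs: empty read sets give all-zero reports; an empty
  fragment list routes all reads to the residual; groups with zero
  variance return a degenerate flag instead of a rank test; zero library
  totals are rejected.
* Ties: leftmost adapter occurrence; smallest ref_id then offset for
  multimapping; smallest modal end; better-supported fragment on
  assignment ties; `sample()`-style RNG is avoided on length-1 index
  vectors.
* Problem sizes: the bundled tests run the full pipeline at 4 × 10^5
  reads with 200 planted features (40 responsive), the trimming oracle
  at 10^4 random reads and the index oracle at 10^4 queries; these sizes
  make binomial sampling error small relative to the 4-fold decision
  boundary while keeping the default suite fast.

# Known limitations

* Exact-substring annotation is faithful to the zero-score-floor
  contract but cannot place reads with sequencing errors; real libraries
  would lose a few percent of reads to the unmapped tier.
* The fold-change rule inherits the motivating design's lack of
  replication; no uncertainty accompanies a differential call.
* Trailer classification is confined to the deposited precursor flanks.
* The generator's references are random sequences: multimapping is far
  rarer than in real ncRNA families, so the deterministic tie-break is
  exercised by dedicated unit fixtures rather than at pipeline scale.
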
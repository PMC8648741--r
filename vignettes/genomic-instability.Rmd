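---
title: "Breakpoint hotspots, instability indexes and survival partitioning: models and choices"
author: "gibreak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint hotspots, instability indexes and survival partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gibreak)
```

## The random breakage model and the Hscore

A cohort of rearranged tumor genomes yields a catalog of structural-variant
breakpoints: point positions, two per SV (one per junction side).  The null
hypothesis worth rejecting is *random breakage*: every readable base pair is
equally likely to carry a breakpoint, so with `n` breakpoints in total and a
readable genome of `L` bp, each base breaks with probability `Pu = n / L`.
The readable size is the total ungapped assembly length: 2,948,611,470 bp
for hg38 (`HG38_READABLE_BP`), and simply the summed chromosome length for
the simulator's gap-free genomes.

For one class of DNA elements the intervals are merged (bedtools-style
union, so overlapping annotations are not double counted), `Li` is the
merged cumulative length and `ni` the number of breakpoints inside (BED
half-open membership: a breakpoint exactly at an interval end is outside).
Under the null the in-class count is `X ~ Binomial(Li, Pu)` and the
**Hscore** is `-log10 P(X > ni)` — strict inequality.  Two numerical
choices matter:

* the tail is evaluated through the log-space survival function of the
  binomial (the regularized-incomplete-beta route used by `pbinom`), never
  by naive pmf summation: realistic inputs have `Li ~ 1e8` and
  `Pu ~ 1e-5`, and observed scores reach several hundred;
* a tail that underflows to exactly zero is reported as an explicit
  infinity flag; matrix/plot exports replace it by a configurable cap
  (default 350, just above the largest representable finite score).
  Published per-cohort analyses report such classes as "Hscore tends to
  infinity", so the flag is information, not an error.

`ni = Li` (more breakpoints than trials is impossible; every base broken)
also yields the infinite flag.  `n_total = 0` is an error: the statistic is
undefined for empty catalogs.

## Hotspots versus hot regions

A large Hscore alone does not distinguish an intrinsically fragile element
class from a class that merely sits in broken neighbourhoods.  Each element
is therefore shifted by ±1, ±2, ... ±8 times its own length (clipped at
chromosome bounds, merged per offset, `Li` recomputed after clipping) and
the Hscore profile over offsets is examined.  The call uses only the
*immediate* neighbours (offsets −1 and +1):

* **hotspot** — center ≥ 3 and both flanks < 3; or all three ≥ 3 and
  center ≥ 1.5 × the larger flank;
* **hot region** — all three ≥ 3 and center < 1.5 × the larger flank;
* **not significant** — center < 3.

The mixed case (exactly one flank ≥ 3) is not covered by the two published
rules; the package resolves it by applying the 1.5-fold rule against the
larger flank and sets a `mixed_flanks` flag so downstream users can see the
interpolation.  When center and the larger flank are both infinite the
ratio is indeterminate and the conservative call is *hot region*.  Shifts
are strand-agnostic (annotation tracks carry no strand here): "+" means
rightward in genome coordinates.  Shifted windows may overlap each other or
the original elements; no exclusion is applied, matching plain
interval-shift semantics.

The cutoff 3 (p = 1e-3) and the 1.5-fold dominance factor are conventions,
exposed as arguments (`h_min`, `fold`) rather than constants.

## Gene context and the instability indexes

Each element is assigned *inside genes* if it overlaps a merged gene body
(TSS–TES, restricted to genes with expression evidence) by at least 1 bp —
whole-element assignment, so element counts are conserved and an element
straddling a gene boundary counts as inside.  Inside and outside sub-tracks
are scored under the same cohort-wide `Pu` and full `L` (one null model for
all territory; nothing in the analysis restricts `L` to genic territory),
and compared through the ratio `RHscore i/o = H_inside / H_outside`.

Classes broken preferentially inside genes are transcription-associated
(TRACe: RLFS, GQ, CpGi, CRM, SCS-S and the four DHS classes); classes
broken regardless of context are replication-associated (RACINe: DR, STR,
MR, IR, Z, SR, MS, LC).  The memberships are fixed constants of the package
(`trace_classes()`, `racine_classes()`) — re-deriving them from a new
cohort is a documented extension, not a default.  `DHS_rest`, the one DHS
class not significantly broken on its own, can be excluded via
`trace_classes(include_dhs_rest = FALSE)`.  APR, SCS-G, LTR and RT belong
to neither index (not enriched).

Each index pools its member BED tracks into one merged territory; a
patient's index value is the Hscore of their own breakpoints against that
territory with `Pu` from their own total breakpoint count (per-patient
normalization makes the index a concentration measure, not a burden
measure).  Per-patient index p-values are used raw — each index is a single
test per patient.  Holm step-down correction is reserved for the
per-patient × per-class matrix (`hscore_matrix(adjust = "holm")`), where
the family is all element classes within one patient, matching the
heatmap context in which that correction is reported.  The published
rescaling of two outlier patients for heatmap display is available only as
an explicit `rescale` export argument and never touches stored results.

## iPART: exhaustive threshold partitioning against survival

Given one scalar per patient and right-censored follow-up, iPART finds the
thresholds that best separate survival groups by minimizing the k-group
log-rank p-value:

1. candidate thresholds are the midpoints between consecutive distinct
   values — the finite set of label-distinct splits ("all possible
   thresholds" up to equivalence);
2. candidates leaving a group below `min_group_size` (default 5; the
   Kaplan–Meier estimate on smaller groups is degenerate) are excluded;
3. for k = 2 the best split is the scan argmin; for k ≥ 3 the candidates
   are the *local minima* of the binary-scan p-curve below `p_cap`
   (default 0.10; a looser 0.3 suits weakly prognostic indexes — both
   values are the published operating points), and every combination of
   k − 1 of them is evaluated;
4. plateaus of equal p collapse to their middle candidate; boundary
   candidates qualify against their single neighbour;
5. ties between combinations break towards the more balanced partition
   (smaller spread of group sizes), then towards smaller thresholds.
   Group labels are `value ≤ t1 → Low`, etc.; with midpoint candidates the
   closed-left convention never matters for observed data.

The minimized p is *not* a valid test of association — it is the minimum of
many correlated tests.  The fitted object prints that caveat, and
`ipart_permutation_p()` reruns the identical search on permuted survival
labels to estimate an honest p (off by default; it multiplies runtime by
the permutation count).  Model selection across k (`ipart_scan_k`) reports
p and the largest hazard ratio for every k from 2 to `k_max` (default 8)
without declaring a winner: the cross-k criterion in the motivating
analyses is informal, so the choice is left to the analyst.

Because the search enumerates thousands of candidate groupings of one
fixed survival sample, the log-rank statistic inside the loops is computed
by a precomputed risk-set engine (at-risk and death-indicator matrices over
distinct death times; each candidate costs two small matrix products).  It
implements the standard k-group log-rank chi-square with the usual tie
correction — identical to `survival::survdiff`, which backs the exported
`logrank_p()` and serves as the reference in the tests.

Hazard ratios per group come from a Cox proportional-hazards fit with group
indicators against a reference group (default: the lowest); groups without
events are flagged with unbounded intervals.  Leave-one-out
cross-validation (`ipart_loocv`) refits the entire search on each n−1
subset and classifies the held-out patient by the refitted thresholds;
infeasible folds yield `NA` labels rather than failing the run.

## MAGIC and treatment stratification

The two 3-group labellings combine into one risk call: **High iff either
index is Medium**.  This encodes the Λ-shaped risk profile — intermediate
instability is the dangerous regime; low instability tumors are indolent
and very high instability appears self-limiting.  Samples missing either
index are excluded with a logged count.  Within each group (of an index or
of MAGIC), `treatment_stratified_survival()` contrasts treated versus
untreated patients (Cox HR, 95% CI, Wald p); strata with fewer than two
patients per arm or zero events are flagged and left unestimated; patients
with unannotated treatment are excluded.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions at desk scale:

| parameter | default | rationale |
|---|---|---|
| genome | 10 chromosomes × 10 Mb, gap-free | keeps every stage at interactive speed while leaving room for 17 element tracks |
| TBPc | log-normal, `meanlog = log(181)`, `sdlog = 0.64`, clipped to [26, 1200], rounded to even | matches the published cohort summary (median 181, mean ≈ 222, observed range); breakpoint sides come in pairs |
| intra-SV fraction | 0.674 | the published share of breakpoint sides on intra-chromosomal SVs |
| element tracks | 120 elements/class, log-normal lengths (`meanlog = log(3000)`) | regulatory-element-scale intervals at a realistic genome fraction |
| enrichment | piecewise-constant density: factor per class territory, 1 elsewhere, renormalized; factors multiply where territories overlap | the simplest generative alternative to the RBM null |
| survival | exponential event times, hazards (Low 0.05, Medium 0.5, High 0.05)/yr; uniform censoring at rate 0.2; 15-year horizon | produces the Λ shape with a tenfold medium-hazard excess and realistic follow-up |

`simulate_cohort()` draws per-patient TRACe and RACINe enrichment factors
as correlated log-normals (correlation 0.6 on the log scale) — both
instability axes grow with overall genomic instability, which is what makes
a combined classifier meaningful — assigns true groups by thresholds on the
resulting iTRAC and keys survival to them.  Everything is deterministic
given `config$seed` and emits its configuration alongside outputs.

Deliberately *not* emulated: SV formation mechanisms (microhomology,
templated insertions), assembly gaps and segmental-duplication masking,
per-chromosome breakpoint covariates, liftover artifacts, and read-level
data.  Consequently, passing tests demonstrate that the statistics and the
search behave as specified under their own model assumptions — they cannot
certify performance on real WGS cohorts, where annotation quality, caller
bias and non-exponential hazards all intrude.

Test and acceptance problem sizes are chosen for interactive turnaround:
calibration uses 500 single-track RBM cohorts of 300 breakpoints on a
100-Mb genome; hotspot power uses factor-5 enrichment in that setting;
hot-region discrimination uses factor-8 enrichment spread over the element
and its ±1..±3 neighbourhoods with 1,000 breakpoints (chosen by a power
calculation so all three windows clear Hscore 3 with margin); threshold
recovery uses 50 cohorts of 200 patients with true thresholds (1, 2) on
uniform(0, 3) values.

## Degenerate inputs and edge behaviour

* empty track → `Li = 0`, tail = `P(X > ni)` over zero trials → Hscore 0
  for `ni = 0`; counting a breakpoint there is impossible.
* all index values identical → the scan has nothing to enumerate and
  errors; similarly fewer than `2 × min_group_size` patients.
* a cohort with zero events → log-rank p = 1 with a warning, never `NaN`.
* duplicate breakpoints at one position all count: no dedup rule is
  imposed beyond whatever the upstream caller applied.
* samples with zero breakpoints are excluded from per-patient indexes with
  a warning (their `Pu` is undefined).

## Known limitations

* The per-patient Holm family (all classes within a patient) and the use
  of raw p for cohort-level profiles are conventions chosen here; other
  family definitions are defensible.
* iPART's minimized p requires the permutation calibration for inference;
  the package reports the optimistic value only because it is the search
  objective.
* MAGIC depends only on the two group labels, so any instability in the
  underlying threshold fits propagates to it; LOOCV is the provided guard.
* The published cohort results (thresholds 0.99/2.29 and 0.74/1.30, the
  stratification p-values, chemotherapy hazard ratios, Pan-Cancer 5-group
  split) require the original WGS/TCGA data and are shipped only as
  reference constants via `lms_reference()`.
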
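---
title: "Diagnosing adhesive capsulitis by model checking radiomic feature patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing adhesive capsulitis by model checking radiomic feature patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acdx)
```

## The problem

Adhesive capsulitis ("frozen shoulder") is a painful restriction of
glenohumeral movement whose MRI diagnosis is difficult even for experienced
musculoskeletal radiologists. acdx implements a fully automatic diagnostic
pipeline that treats an MRI exam not as an image to be classified by a
learned model, but as a *formal system* whose behaviour can be verified:
quantitative texture descriptors are extracted slice by slice, discretized
to three levels, assembled into a small process-algebra model of the exam,
and checked against temporal-logic formulas that encode the levels at which
disease signs appear. The model checker's binary verdict *is* the
diagnosis.

The appeal of this construction is that the diagnostic rule is an explicit,
human-readable logical formula rather than an opaque decision function, and
that verification is exhaustive over the model's state space — there is no
training step and no stochastic inference at diagnosis time.

## Pipeline overview

1. **Feature extraction** (`compute_first_order()`, `compute_glcm()`,
   `compute_glcm_features()`, `slice_features()`): per-slice radiomic
   features. Six classes are bookkept (first-order, GLCM, GLDM, GLRLM,
   GLSZM, NGTDM; 94 features in total), of which 30 selected features —
   five per class, with shape descriptors replacing NGTDM — form the
   working set (`feature_registry()`). Only first-order and GLCM features
   are computed natively; the other classes arrive via feature tables from
   any IBSI-style extractor (`read_feature_table()`).
2. **Discretization** (`fit_discretization()`, `discretize_features()`):
   every feature is mapped to low / medium / high by cohort-pooled
   empirical tertiles.
3. **Model building** (`build_ccs_model()`, `lts_from_model()`): each slice
   becomes a process performing one action per feature (e.g. `H_variance`),
   with all orderings interleaved; processes chain through the slices and
   end in `nil`. The model expands to a finite labeled transition system
   (LTS).
4. **Signature checking** (`slice_pattern()`, `compile_pattern()`,
   `check_formula()`, `classify_patient()`): a disease signature — "these
   features at these levels, in at least one slice" — compiles to a
   temporal-logic formula checked against the LTS of each imaging plane;
   plane verdicts combine with OR.
5. **Evaluation** (`evaluate_cohort()`, `metrics_from_counts()`,
   `counts_from_metrics()`): confusion matrices and
   accuracy/precision/recall/specificity, plus exact recovery of integer
   confusion matrices from published four-decimal metric triples.
6. **Synthesis** (`synthesize_cohort()`, `calibrate_fixture()`,
   `generate_phantom()`): seeded generators producing cohorts with planted
   signatures, so the full pipeline is exercisable and testable without
   clinical data.

## Texture features

First-order features are plain functionals of the masked intensity
distribution: Energy $\sum x_i^2$ (no intensity shift), Total energy
(Energy scaled by voxel volume in mm³), Minimum, Median and Variance.
Two conventions are pinned for reproducibility: variance is the
*population* variance (divide by $N$), and the median of an even count is
the midpoint-interpolated order statistic.

The gray-level co-occurrence matrix $P_\delta(i,j)$ counts how often levels
$i$ and $j$ occur in pixel pairs separated by a displacement $\delta$.
Intensities are first quantized by equal-width binning of the in-mask range
into `n_levels` bins (default 32; a constant image maps to level 1). The
default displacement set is the four unique 2-D directions at distance 1
(0°, 45°, 90°, 135°); matrices are symmetrized and normalized, and feature
values are averaged across displacements, the standard practice when no
direction is privileged. From the normalized symmetric matrix we compute
Contrast, Cluster prominence, Difference average, Difference variance and
Inverse difference (Id). Equal-width binning, distance 1 and the four-angle
average are defaults chosen because they are the common radiomics
convention; all are parameters, not constants.

Masks default to the whole slice (the pipeline's native mode); a
threshold-derived ROI mask can be supplied to `image_region()` instead.
Both modes are supported because either may be appropriate depending on how
exams were acquired and segmented.

## Discretization

Levels must be comparable across patients, so thresholds are fitted on a
reference cohort and frozen (`write_scheme()` / `read_scheme()`), never
refitted per patient — refitting would leak the evaluation cohort into the
rule. With three levels and no prior scale for each feature, the
minimal-assumption choice is empirical tertiles pooled over every slice of
every cohort patient and both imaging planes: $t_1$ and $t_2$ are the
smallest observed values at or above the 1/3 and 2/3 empirical fractions,
and a value $x$ maps to L if $x \le t_1$, M if $t_1 < x \le t_2$, H
otherwise. Boundary values belong to the lower level; a cohort-constant
feature collapses to $t_1 = t_2$ and maps everything to L with a warning.
Pooling across planes (rather than per plane or per patient) is itself a
design choice: it keeps a single scheme per feature and makes the level
vocabulary identical in both planes, which the OR-combination of plane
verdicts implicitly assumes.

## The formal model

A discretized exam with $n$ slices and $k$ active features becomes $n$
processes $P_1 \ldots P_n$ plus $P_{n+1} = \mathrm{nil}$; $P_i$ offers all
$k!$ orderings of slice $i$'s actions as alternative prefix chains ending
in $P_{i+1}$. Including every ordering (interleaving) makes the order of
features within a slice semantically irrelevant — only the *set* of levels
matters. The grammar deliberately covers just this fragment of CCS (prefix,
choice, constants, `nil`); parallel composition, restriction and
relabelling are rejected, because patient models never use them.

Materializing $k!$ summand chains is wasteful, so the LTS uses a subset
construction: a state is (slice $i$, set $S$ of already-performed actions),
offering each remaining action and moving to the next slice's entry state
(or the final state) when the set completes. Because a slice's actions
commute, this is strongly bisimilar to the naive permutation-tree
expansion — the test suite verifies bisimilarity directly for $k \le 4$ —
and has exactly $n(2^k - 1) + 1$ states for uniform $k$: 528 states for a
typical 17-slice, 5-feature exam, versus 120 summands per slice if
expanded. Serialization still emits the full permutation set (capped at
$k \le 6$ unless `allow_huge = TRUE`, since $7! = 5040$ summands per line
stops being useful text).

## The logic and the checker

Formulas are built from `tt`, `ff`, negation, conjunction, disjunction,
labelled diamond `<A>φ` ("some transition in label set A leads to a state
satisfying φ") and box `[A]φ`, and the derived temporal operators `EF`
(eventually, on some path), `AG` (always, on all paths) and `EX` (some next
state). Label sets may use `*` wildcards over the level or feature part.
`check_formula()` evaluates formulas bottom-up as state sets; `EF` is the
least fixpoint of backward reachability and `AG` the greatest fixpoint of
invariance, iterated to stabilization — on these acyclic models at most
one round per state, and at the pipeline's scale (~700 states) plain set
iteration is faster than any symbolic representation would pay for. A
satisfied `EF` formula carries a shortest witness path, which is the
clinically useful part of a positive verdict: *which* slice showed the
signs. No external model-checking tool is bound; the evaluator is
self-contained and is itself validated against a naive path-semantics
oracle on thousands of random models.

A label that resolves to nothing in a model's alphabet is treated as the
empty set (diamond false, box true) with a warning; the classifier
suppresses the warning because compiled signatures routinely mention levels
a particular exam never exhibits.

## Signatures and their compilation

A slice pattern constrains some features of one class to allowed level
sets; a signature holds one pattern per imaging plane, and a patient is
positive when *at least one* plane's pattern holds. For the default
`min_slices = 1`, a pattern compiles to

$$\mathrm{EF}\Big(\bigwedge_{f} \langle\, \ell_f : \ell \in \text{allowed}(f) \,\rangle\, tt\Big)$$

— a conjunction of enabled diamonds under one `EF`, *not* a sequential
diamond chain. The distinction is load-bearing: a chain
`<H_contrast><L_id>tt` can be witnessed by the last action of slice $i$
followed by the first action of slice $i+1$, silently matching a pattern no
single slice exhibits, whereas a conjunction of diamonds can only hold at a
state where all those actions are simultaneously enabled, and every enabled
action at any state belongs to the current slice. The equivalence
"compiled verdict = does some slice satisfy all constraints" is tested
against a direct table scan on thousands of random exams; it is the single
property the whole pipeline leans on.

Persistence (`min_slices > 1`, optionally `consecutive`) is handled by
counting slice-entry states that satisfy the conjunction rather than inside
the logic, since a counting quantifier is not expressible with these
operators alone.

The shipped `default_glcm_signature()` (Contrast H, Cluster prominence H,
Id L on either plane) is an explicitly-marked placeholder: a plausible
"coarse, high-contrast texture" rule, not a validated clinical formula. The
honest route to a real signature is `mine_candidate_patterns()`, which
enumerates all single-level constraint conjunctions over a class's five
features (at most $4^5 - 1 = 1023$ candidates) and returns those matched by
at least a support fraction of radiologist-selected exemplar patients,
largest and best-supported first.

## Evaluation arithmetic

Metrics are exact rationals; reporting rounds half-up at four decimals.
`counts_from_metrics()` inverts a printed (precision, recall, specificity)
triple over a known cohort split by exhaustive search over
$tp \in 0..n_{pos}$, $fp \in 0..n_{neg}$, with an absolute tolerance of
$10^{-4}$ — wide enough to absorb both rounding and truncation of
four-decimal printing (e.g. $14/18 = 0.7\overline{7}$ printed as 0.7777) —
and requires the solution to be unique, erroring on both inconsistency and
ambiguity. Macro-averaged metrics over several readers are deliberately
not invertible this way and are out of scope.

## The synthetic cohort generator

The generator emulates the structure of a two-plane shoulder-MRI radiomics
cohort — by default 32 positive and 23 negative patients, about 22 slices
per patient per plane (jittered ±4, since an average slice count implies
variation), all 30 selected features. It makes no claim of clinical
realism: marginal distributions of real radiomic features are not public,
and the generator's purpose is to exercise the pipeline's machinery, not to
simulate shoulders. Phantom images (`generate_phantom()`) likewise provide
only the qualitative guarantee that smooth-gradient regions score lower
GLCM contrast than high-amplitude noise regions.

Two design decisions matter:

* **Planting operates on continuous values.** A patient meant to test
  positive gets `min_slices` slices (in one randomly chosen plane) whose
  constrained features draw from allowed-level clusters; a patient meant to
  test negative has all but `min_slices - 1` slices of every signature
  plane "broken" by drawing one constrained feature from a disallowed
  level. The discretizer, model builder and checker then run for real —
  labels are never injected downstream.
* **Level clusters are separated and count-balanced.** Values draw from
  truncated Gaussians at means −2/0/+2 (sd 0.5, truncated at 1.4 sd), so
  the three clusters occupy disjoint intervals; and each feature's intended
  level counts are balanced to the exact tertile quotas
  ($\lceil N/3 \rceil$, $\lceil 2N/3 \rceil - \lceil N/3 \rceil$, rest)
  that `fit_discretization()`'s quantile definition implies. Together these
  make tertile discretization recover *every* intended level
  deterministically, which in turn lets `calibrate_fixture()` guarantee —
  and assert, by re-running the classifier — that a requested confusion
  matrix is realized exactly rather than approximately. Real data offers no
  such guarantee, which is precisely why the assertion is built in: a
  fixture that silently drifted from its target would poison every
  downstream check.

Everything is a deterministic function of the specification and one
integer seed.

## What passing tests do and do not show

The test suite establishes that the machinery is correct: feature formulas
match hand calculations and brute-force pair counting; the subset LTS is
bisimilar to the naive expansion; the fixpoint checker agrees with
exhaustive path semantics on thousands of random model/formula pairs;
compiled signatures agree with direct slice scans; printed cohort metric
triples invert to unique integer confusion matrices; and a calibrated
55-patient synthetic cohort reproduces the reference combined-plane metrics
(accuracy 0.7455, precision 0.8214, recall 0.7188, specificity 0.7826) end
to end. None of this validates the *clinical* discriminative power of any
particular signature on real MRI data — that requires the real cohort and
a recalibrated signature, which is exactly the boundary between what a
synthetic cohort can and cannot certify.

Problem sizes used by the default test run were chosen to keep the suite
quick while still exercising every equivalence on nontrivial inputs:
oracle comparisons run on models with up to 3 slices and 3 features
(the equivalences are structural, so small models cover all state shapes),
random-target fixture checks on cohorts of ~5–7 patients with 5 slices,
and the full 55-patient fixture once.

## Known limitations

* Only first-order and GLCM features are computed natively; GLDM, GLRLM,
  GLSZM and shape features must be ingested from an external extractor's
  tables. Shape features in particular are never computed (the selected-30
  registry includes them for bookkeeping fidelity).
* The feature-selection step that produced the canonical 30-feature list is
  not reproducible from public information; the list ships as a static
  registry, with `filter_features()` (near-zero variance, then pairwise
  |r| > 0.95 pruning) as a generic fallback for new cohorts.
* The logic has no counting or fairness operators; persistence constraints
  live outside the formula.
* Single-class mode is enforced throughout: a signature cannot mix feature
  classes in one model.
* Synthetic cohorts are structural stand-ins; no claim about real-data
  feature distributions is made or implied.
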
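# acdx

Automatic diagnosis of adhesive capsulitis of the shoulder ("frozen
shoulder") from slice-wise radiomic features of MRI exams, by formal
verification instead of statistical learning.

The package is aimed at researchers in quantitative medical imaging who
want a diagnostic rule that is an explicit logical formula — auditable,
exhaustive over the exam, with a witness slice for every positive call —
rather than a trained classifier.

## The method

For each patient and imaging plane (coronal, sagittal):

1. **Radiomic features per slice.** First-order statistics and gray-level
   co-occurrence matrix (GLCM) texture features are computed natively
   (Energy, Median, Minimum, Total energy, Variance; Contrast, Cluster
   prominence, Difference average, Difference variance, Id); the GLCM
   `P_δ(i,j)` counts level pairs at displacement δ over the four unit
   directions, symmetrized and normalized. Other feature classes (GLDM,
   GLRLM, GLSZM, shape) are ingested from any IBSI-style extractor's
   tables. The working set is the canonical 30-feature registry, five per
   class.
2. **L/M/H discretization.** Each feature is cut at cohort-pooled
   empirical tertiles `(t1, t2)`: `x ≤ t1 → L`, `t1 < x ≤ t2 → M`,
   `x > t2 → H`. Schemes are fitted once and frozen to YAML.
3. **CCS model.** The exam becomes a process-algebra term: one process per
   slice performing one action per feature (`H_variance`, `L_id`, ...),
   all orderings interleaved, chained through the slices and terminated by
   `nil`:

   ```
   proc P1=H_variance.H_energy.H_median.H_minimum.H_totalenergy.P2+...
   ...
   proc P18=nil
   ```

   The model expands to a finite labeled transition system with
   `n(2^k − 1) + 1` states (528 for 17 slices × 5 features).
4. **Model checking.** A disease signature — features at levels, e.g.
   Contrast H ∧ Cluster prominence H ∧ Id L — compiles to a temporal-logic
   formula `EF(<H_contrast>tt & <H_clusterprominence>tt & <L_id>tt)`,
   checked by a fixpoint evaluator (diamond/box modalities plus EF/AG/EX).
   TRUE means some slice shows all the signs; plane verdicts combine with
   logical OR; TRUE = capsulitis.
5. **Evaluation.** Confusion matrices and accuracy / precision / recall /
   specificity, plus exact recovery of integer confusion counts from
   published four-decimal metric triples
   (`counts_from_metrics(32, 23, 0.8214, 0.7188, 0.7826)` → TP 23, FP 5,
   FN 9, TN 18).

A seeded synthetic-cohort generator (`synthesize_cohort()`,
`calibrate_fixture()`) plants signatures into continuous feature values so
the entire pipeline is testable without clinical data, including cohorts
calibrated to an exact target confusion matrix.

## Worked example

```r
library(acdx)

co     <- synthesize_cohort(n_pos = 5, n_neg = 4, slices_per_patient = 8,
                            seed = 42)
scheme <- fit_discretization(co$features)
glcm   <- co$features |>
  discretize_features(scheme) |>
  select_features("GLCM")

m <- build_ccs_model(glcm[glcm$patient_id == "pt001" &
                          glcm$plane == "coronal", ])
m
#> <acdx_ccs> pt001 (coronal): 4 slices, 5 actions/slice, 5 processes (P5 = nil)

lts <- lts_from_model(m)
lts
#> <acdx_lts> 125 states, 320 transitions, alphabet of 14 actions

sig <- default_glcm_signature()   # placeholder rule; recalibrate on real data
check_formula(lts, compile_pattern(sig$patterns$coronal), quiet = TRUE)
#> <acdx_verdict> TRUE
#>   witness: M_clusterprominence.H_contrast.H_differenceaverage.
#>            L_differencevariance.L_id.H_clusterprominence.L_contrast.
#>            M_differenceaverage.M_differencevariance.H_id

ev <- glcm |> classify_cohort(sig) |> evaluate_cohort(co$labels)
ev
#> <acdx_eval>
#>  <acdx_confusion> TP 5  FP 0  FN 0  TN 4
#>   accuracy 1.0000  precision 1.0000  recall 1.0000  specificity 1.0000
```

The verdict's witness is the action path to the first state where every
constrained sign is simultaneously enabled: here the checker walked through
slices 1–2 and found the signs (Contrast H, Cluster prominence H, Id L)
at slice 3. The synthetic cohort is planted to be perfectly classifiable,
hence the identity metrics; `calibrate_fixture()` instead realizes any
requested confusion matrix exactly.

Real signatures should be mined from exemplar patients rather than
hand-written: `mine_candidate_patterns()` enumerates all level-constraint
conjunctions over a class's features and keeps those shared by the
exemplars.

A thin command-line wrapper over these functions ships in
`inst/cli/acdx.R` (`simulate`, `discretize`, `build-model`, `check`,
`calibrate`, `evaluate` subcommands).

## Formula grammar

```
formula  := conj ('|' conj)*
conj     := unary ('&' unary)*
unary    := '!' unary | 'EF' '(' formula ')' | 'AG' '(' formula ')'
          | 'EX' '(' formula ')' | '<' labels '>' unary
          | '[' labels ']' unary | 'tt' | 'ff' | '(' formula ')'
labels   := label (',' label)*        # H_contrast, H_*, *_id, ...
```

See `vignettes/acdx-methods.Rmd` for the full account of the model, the
compilation of signatures into formulas, the generator's design and the
package's limitations.
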
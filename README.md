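# pronomorph

Linear versus outline-based morphometry of the cimicid pronotum.

Cimicidae — bed bugs, bat bugs and swallow bugs — are blood-feeding
ectoparasites of medical and veterinary importance whose species are
notoriously hard to tell apart. The pronotum (the dorsal plate of the first
thoracic segment) is sturdy, easy to photograph, and taxonomically
informative. `pronomorph` implements, as a tested and reusable pipeline,
the full comparison of the two standard ways of quantifying it:

- **Linear branch** — three measurements (width `pw`, medial length `pm`,
  anterior concavity depth `pc`, in µm) decomposed à la Darroch–Mosimann
  into log-size, `logsize = (log pw + log pm + log pc)/3`, and two
  size-free log-shape ratios (LSR1, LSR2): the scores on the non-null
  principal components of the row-centered log measurements.
- **Outline branch** — closed pseudolandmark contours decomposed by
  elliptic Fourier analysis (Kuhl–Giardina closed-form sums, chord-length
  parametrization). Size is the semi-major axis of the first-harmonic
  ellipse; shape is the normalized (NEF) coefficient set with
  `a*1 = 1, b*1 = c*1 = 0`, i.e. `4H − 3` free variables at `H` harmonics
  (default `H = 7`).

Both branches, always stratified by sex, feed the same battery:
permutation ANOVA on size (classical F-ratio, label permutations,
`p = (b+1)/(n_perm+1)`), leave-one-out validated reclassification
(Gaussian maximum likelihood on size; a 3-hidden-unit backpropagation MLP
on shape, 10 repeated LOO cycles), UPGMA clustering with optimal
cluster-to-species concordance, and allometry (R² of shape variables
regressed on size).

Specimen data of this kind are typically available only on request, so the
package includes a synthetic pronotum generator (`synth_config()`,
`generate_dataset()`) that emulates the relevant three-species × two-sex
study design — including sexual size dimorphism, species-specific anterior
excavation and lateral lobe elongation, allometric drift and digitization
noise — and whose parameters are recoverable ground truth for the
measurement operator. Everything is testable end to end without any
specimen images.

## Worked example

```r
library(pronomorph)

ds  <- generate_dataset(synth_config(seed = 42))   # 78 synthetic specimens
cfg <- pipeline_config(seed = 42)
rep <- compare_methods(run_linear_branch(ds, cfg),
                       run_outline_branch(ds, cfg))
print(rep)
```

```
== Size panel ==
        species    sex  method  n   mean_size      sd_size letters
1         cimex   male  linear  7    6.673944   0.16241836       a
2     paracimex   male  linear 14    6.231819   0.06812362       b
3  stricticimex   male  linear 12    5.604012   0.16503425       c
...
== Validated reclassification ==
   method    sex size_ml_pct size_ml_label shape_mlp_pct shape_mlp_sd
1  linear   male     96.9697   97% (32/33)      78.78788     3.779452
2  linear female    100.0000  100% (45/45)      72.66667     1.073435
3 outline   male     96.9697   97% (32/33)      92.72727     2.555376
4 outline female    100.0000  100% (45/45)      94.66667     2.388817
...
== Allometry (R2, %) ==
   method    sex shape_var     r2_pct
1  linear   male      LSR1 80.4285619
...
5 outline   male       PC1  1.2194978
```

Reading it: the size panel gives per-group means ± SD of each branch's
size variable with compact significance letters from the pairwise
permutation ANOVAs (groups sharing a letter are not significantly
different at α = 0.05). The reclassification panel reports leave-one-out
validated accuracies — size-based maximum likelihood as a percentage with
raw counts, shape-based MLP as mean ± SD over 10 repeated LOO cycles. The
allometry panel shows how much of each shape variable size explains: on
this synthetic design, as on real material, the linear shape variables are
heavily size-contaminated (LSR1 ≈ 80 %) while the NEF principal components
are much less so.

Individual stages are exported too: `read_tps()` / `read_measurements_csv()`
for real data, `fit_efa()`, `normalize_efa()`, `semi_major_axis()`,
`inverse_efa()`, `mean_shape()`, `log_shape_ratios()`,
`permutation_anova()`, `ml_size_classify_loo()`, `mlp_loo_classify()`,
`upgma()`, `cluster_concordance()`, `allometry_r2()`,
`export_mean_shapes()`, `write_newick()`.

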
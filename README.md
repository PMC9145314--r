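# npinflam

Benchmark-dose modelling and transcriptomics for in vitro nanoparticle
inflammasome screening.

Engineered nanomaterials can trigger the NLRP3 inflammasome — a
caspase-1-activating complex whose readouts are falling cell viability and
rising IL-1β/IL-18 secretion — and whether they do depends on particle
shape and surface chemistry. Screening studies of this kind expose
PMA-differentiated THP-1 macrophages (wildtype and ASC- or NLRP3-deficient)
to dilution series of gold nanorods, nanostars and nanospheres, read out
WST-1 viability and cytokine ELISAs, summarize each dose–response curve as
a benchmark dose, and then profile gene expression of exposed cells on
one-colour microarrays with pathway-level enrichment. `npinflam` implements
that entire computational chain as a tested R package for analysts who run
such screens:

- **Benchmark-dose modelling** (`fit_mle`, `select_model`,
  `goodness_of_fit`, `compute_bmd`, `profile_ci`, `model_average`,
  `bmd_analysis`): maximum-likelihood fits of the two nested five-member
  families used in regulatory dose–response software,

  E1: *y* = *a* · · · E5: *y* = *a*[*c* − (*c*−1)e^(−*bx*^*d*)],
  H1: *y* = *a* · · · H5: *y* = *a*(1 + (*c*−1)*x*^*d*/(*b*^*d*+*x*^*d*)),

  under log-normal errors; likelihood-ratio selection along the nesting
  chain 1 → 2 → {3,4} → 5; a saturated-model goodness-of-fit check;
  closed-form BMDs at a run-time benchmark response (BMR, default 0.10);
  90% profile-likelihood BMDL/BMDU (drop of χ²₁(0.90)/2 = 1.353); and
  geometric model averaging with a min-BMDL/max-BMDU pooled interval.
- **Plate-assay arithmetic** (`viability_percent`, `fit_5pl`, `invert_5pl`,
  `elisa_plate_analysis`, `endotoxin_classify`, `dose_convert`,
  `log2_dose`, `surface_to_volume`): WST-1 normalization, five-parameter
  logistic ELISA calibration with analytic inversion and out-of-range
  flags, endotoxin threshold classification (A/B/C), nM → µg/mL dose
  conversion and particle surface-to-volume geometry.
- **Microarray pipeline** (`filter_reliable`, `log2_quantile_normalize`,
  `collapse_by_symbol`, `differential_expression`, `select_degs`,
  `estimate_fdr`, `pca_scores`, `log2fc_heatmap`): five-criteria feature
  reliability filtering, log2 + quantile normalization, median collapse by
  gene symbol, per-comparison Student t-tests, DEG union at *p* < 0.001
  with an expected-false-positives FDR estimate, PCA and clustered log2FC
  heatmaps.
- **GSEA** (`rank_genes`, `enrichment_score`, `permutation_significance`):
  weighted Kolmogorov–Smirnov running-sum enrichment with a gene-label
  permutation null, NES and BH q-values.
- **Synthetic data with ground truth** (`gen_dose_response`,
  `gen_elisa_plate`, `gen_expression`, `default_spikes`,
  `default_set_shifts`): seeded generators for every input the pipeline
  needs, writing the generating truth beside the data.
- **Orchestration** (`validate_config`, `run_pipeline`): a config-driven
  end-to-end run with per-stage logs and a checksummed manifest.

## Worked example

Simulate a nanorod-like viability series (three-parameter exponential
decline, 10% benchmark response) and recover its benchmark dose:

```r
library(npinflam)

truth <- dr_model("exponential", 3, a = 100, b = -0.002, d = 1.5)
compute_bmd(truth, bmr = 0.10, direction = "decreasing")
#> [1] 14.05288

d  <- gen_dose_response(truth, sd = 0.05, seed = 3)   # 6 doses + control, 3 reps
an <- bmd_analysis(d, bmr = 0.10)
an
#> <bmd_analysis bmr=0.1>
#> <bmd_result: BMD 13.64, 90% CI [12.04, 15.37], models: E3>
#>   note: hill family: selected model rejected by full-model GOF (p = 0.00271)
```

The LRT chain picks the three-parameter exponential member (the generating
form), the saturated-model test accepts it, and the profile-likelihood 90%
interval [12.0, 15.4] covers the true benchmark dose 14.05; the Hill family
is honestly rejected by the goodness-of-fit check on this draw. Plate-level
arithmetic is equally direct:

```r
rod <- particle_geometry("rod", radius = 7, length = 60, mass_per_nM = 1.324)
dose_convert(25, rod)                       # 33.1 ug/mL at 25 nM
round(surface_to_volume(rod), 2)            # 0.32 /nm (flat-capped cylinder)
endotoxin_classify(0.030, product_conc = 100, limit = 0.5)   # "A"
```

## The analysis workflow

`analysis/` holds the numbered drivers that reproduce the study-style
analysis end to end on synthetic data (run them in order from the
repository root; outputs land under `results/`):

| script | what it does |
|---|---|
| `01_synthetic_data.R` | dose–response series per particle shape (3 pooled experiments each), an ELISA plate, a 10,246-gene × 24-sample expression experiment, gene sets — all with ground-truth sidecars |
| `02_assay_processing.R` | 5PL calibration + inversion, endotoxin A/B/C table, dose conversions, surface-to-volume ratios |
| `03_bmd_modelling.R` | per-endpoint model selection, GOF, ED10 with profile bounds, model averaging |
| `04_microarray.R` | filter → normalize → collapse → t-tests → DEG union/FDR → PCA → clustered heatmap |
| `05_gsea.R` | per-comparison enrichment and the repeatedly-significant summary grid |

On the default seed the chain recovers the generating truths: rod viability
ED10 13.9 (truth 14.05) with 90% CI [12.7, 15.3], rod IL-1β ED10 3.19
(truth 3.18), no dose–response relationship for the flat star/sphere
endpoints, and rod-specific downregulation of the
cholesterol-synthesis-like and oxidative-phosphorylation-like sets at the
permutation floor (NES ≈ −2.8, p = 0.001) with the cell-cycle-like set up
under star/sphere exposure.

`run_pipeline(list(out_dir = "results/pipeline"))` runs a smaller
config-driven version of the same chain and writes a manifest with md5
checksums; identical config and seed give identical checksums.

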
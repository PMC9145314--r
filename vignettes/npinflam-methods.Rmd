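---
title: "Methods: benchmark-dose modelling and transcriptomics for nanoparticle inflammasome screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmark-dose modelling and transcriptomics for nanoparticle inflammasome screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npinflam)
```

`npinflam` implements the computational chain of an in vitro nanoparticle
inflammasome screen: plate-assay arithmetic (WST-1 viability, 5PL ELISA,
endotoxin classification, dose-metric conversion), benchmark-dose (BMD)
modelling of the resulting dose–response curves, a one-colour microarray
differential-expression pipeline, and gene set enrichment analysis (GSEA).
A seeded synthetic-data generator supplies every input with known ground
truth, so each stage can be validated by recovery rather than by eyeballing.

## Dose–response model families

A continuous endpoint $y$ (viability as % of control, or a cytokine
concentration in pg/mL) is modelled as a function of dose $x$ with two
nested five-member families, the standard choice in regulatory
benchmark-dose software:

Exponential family:
$$\mathrm{E1}: y = a \qquad \mathrm{E2}: y = a e^{bx} \qquad
\mathrm{E3}: y = a e^{bx^d}$$
$$\mathrm{E4}: y = a\left[c - (c-1)e^{-bx}\right] \qquad
\mathrm{E5}: y = a\left[c - (c-1)e^{-bx^d}\right]$$

Hill family:
$$\mathrm{H1}: y = a \qquad
\mathrm{H2}: y = a\left(1 - \tfrac{x}{b+x}\right) \qquad
\mathrm{H3}: y = a\left(1 - \tfrac{x^d}{b^d+x^d}\right)$$
$$\mathrm{H4}: y = a\left(1 + (c-1)\tfrac{x}{b+x}\right) \qquad
\mathrm{H5}: y = a\left(1 + (c-1)\tfrac{x^d}{b^d+x^d}\right)$$

$a > 0$ is the background response (every member equals $a$ at $x = 0$),
$b$ the potency/sensitivity parameter, $c \ge 0$ the asymptote factor
(levels 4–5 plateau at $a \cdot c$), and $d \in [1, 4]$ a shape exponent.
The four- and five-parameter exponential members are written in the
canonical saturating form above because only this form preserves the
nesting structure the likelihood-ratio selection requires (E2 is E4 with
$c = 0$ and the sign of $b$ flipped; E3 is E5 the same way; H2/H3 are H4/H5
at $c = 0$), and H3/H5 use $b^d$ so that $b$ keeps dose units. $b$ is
sign-free in the exponential family so both falling viability and rising
cytokine curves fit; the Hill $b$ is a positive half-effect-type dose. The
bound $d \le 4$ avoids infinite-slope fits on six-point designs; $d \ge 1$
keeps the curve differentiable at the origin.

### Likelihood and fitting

Responses are positive and right-skewed, and the BMD summary below uses
geometric averaging, so the error model is log-normal with a homoscedastic
log-scale standard deviation: $\log y_{ij} \sim N(\log f(x_i), \sigma^2)$.
Maximizing this likelihood is nonlinear least squares on $\log y$;
$\sigma^2$ is profiled analytically, and because $a$ enters every member
multiplicatively its MLE given the shape parameters is
$\exp\{\overline{\log y - \log h(x)}\}$ with $f = a\,h$. Each fit therefore
optimizes at most three shape parameters. Optimization is deterministic
multi-start local search: starts are derived from data quantiles (control
geometric mean, top/control ratio, dose range), a warm start from the
nested parent model is always included (which also enforces the nesting
monotonicity of the maximized log-likelihoods), and one-parameter members
are solved on a signed log-spaced grid followed by local refinement —
the objective is multiscale in $b$, whose natural size depends on the dose
range.

### Model selection, goodness of fit, BMD

Selection walks the nesting chain $1 \to 2 \to \{3, 4\} \to 5$; an
extension is kept only when the likelihood-ratio statistic exceeds the
$\chi^2$ critical value at $\alpha = 0.05$ with degrees of freedom equal to
the added parameter count. The selected member is then compared to the
"full" (saturated) model — per-dose-group means on the log scale — and
accepted when that LRT gives $p > 0.05$.

The BMD at benchmark response (BMR) $q$ solves $f(x) = a(1 \mp q)$ in the
direction of the fitted curve; all ten members invert in closed form. The
BMR is a run-time parameter: the analysis drivers default to 0.10 (the
"ED10" flavour of the reported effective doses) and 0.50 is equally valid
for the steep cytokine curves; neither is hard-coded. 90% confidence bounds
come from the profile likelihood: the model is reparameterized so the BMD
is explicit ($b$ is expressed in terms of the BMD, the BMR and the other
parameters), the remaining parameters are re-maximized at each fixed BMD,
and BMDL/BMDU are where the profile drops $\chi^2_1(0.90)/2 = 1.353$ below
its maximum. A profile that never drops on one side yields an explicit
one-sided bound (0 or $\infty$). When both families yield an accepted
member, the pooled BMD is the geometric mean of the per-model BMDs and the
pooled 90% interval spans the smallest BMDL to the largest BMDU.

Replicate experiments are pooled with the experiment identifier retained,
matching how the reported tables were produced; no between-experiment
random effect is modelled.

### Numerical behaviour and known limitations

The profile bounds were verified against a brute-force oracle (200
constrained grid refits per fixture, crossing read off by interpolation)
to within 2%, and fits against their own nested warm starts to a $10^{-6}$
log-likelihood tolerance. Coverage of the 90% profile interval, measured at
the generating model over seeded simulations (six-point two-fold design,
three replicates, log-scale sd 0.05), is about 86–87% at $n = 21$
observations and reaches the nominal 90% by ten replicates per dose: the
$\chi^2$ cutoff with a profiled variance is slightly anti-conservative in
small samples. Two further small-sample effects are worth knowing about.
First, the saturated-model goodness-of-fit LRT over-rejects at this design
size (roughly 20% at a nominal 5%), so a minority of perfectly ordinary
datasets are reported as "no accepted model" — visible occasionally in the
analysis drivers. Second, the LRT chain occasionally escalates to the
five-parameter member on noise, and the conditional interval of an
overfitted member can miss the true BMD; the post-selection pooled interval
therefore covers slightly below nominal. Both are properties of the
prescribed procedure, not of this implementation, and both shrink with
replication.

## Plate-assay arithmetic

Viability is the WST-1 ratio
$(A_{\text{cells},X} - A_{\text{medium},X}) /
(A_{\text{cells},C} - A_{\text{medium},C}) \times 100$
on background-corrected absorbances ($A_{440} - A_{620}$), replicate wells
averaged before the ratio; the statistic is invariant to a common positive
gain. ELISA calibration uses the five-parameter asymmetric logistic
$y = L + (U - L)\,/\,\{1 + (x/c)^{-b}\}^{g}$ with uniform weighting (the
assay description names only "5-parameter curve fitting"); blanks enter at
concentration 0 and anchor $L$, and inversion is analytic between the
asymptotes with out-of-range optical densities flagged rather than clipped.
Sample pre-dilution (20-fold by default) multiplies the inverted
concentration. Endotoxin outcomes classify a measured EU/mL value against
the limit-times-product-concentration threshold (0.5 EU/mg at 100 µg/mL
gives 0.05 EU/mL), with particle interference forcing the "no accurate
measurement" class; because no recovery window is stated for the spiked
controls, the interference flag is an input, and an optional helper flags
spike recovery outside the conventional 50–200% LAL window. Dose-metric
conversion multiplies a particle number concentration (nM) by the
particle-specific mass factor (µg/mL per nM, e.g. 1.324 for the 60 × 14 nm
rod); the conversions reproduce the printed worked values verbatim without
reinterpreting the source's nM/µM unit inconsistency. Surface-to-volume
ratios treat rods as flat-capped cylinders, $2(r + h)/(rh)$, and spheres as
$3/r$.

## Microarray pipeline

Features are kept when all five scanner quality criteria hold (above noise,
below saturation, not a population outlier, uniform spot, not a control
feature); the outlier and uniformity flags are consumed, not computed —
they come from the feature-extraction software, and the synthetic generator
fabricates them. Intensities are log2-transformed and quantile normalized
(limma's implementation; afterwards every sample shares one empirical
distribution and within-sample ranks are preserved), then collapsed to one
row per gene symbol by the per-sample median — robust to a single bad
probe; the aggregation is the package's choice since only "collapsed by
gene symbol" is specified. Each exposure is compared to its control by a
two-sample equal-variance t-test on log2 values (the conventional reading
of "t-test" for $n = 3$ groups; Welch is available), and the DEG set is the
union of genes with $p < 0.001$ in any comparison. The FDR estimate is
expected false positives over observed calls,
$(\text{comparisons} \times \text{genes} \times \alpha) / \text{calls}$ —
a reconstruction chosen because it reproduces the published 11% from the
published per-comparison counts (71.7/656); it is documented as an
inference, not as the original authors' formula. PCA is a centred,
unscaled SVD of the samples in DEG space; heatmaps show per-comparison mean
log2 fold changes with genes ordered by hierarchical clustering (Euclidean
distance, average linkage — common defaults, both configurable).

## Gene set enrichment

Genes are ranked by the signed t-statistic (descending; ties broken
lexicographically so the ranking is deterministic, and infinite statistics
from zero-variance genes are placed just beyond the finite extremes). The
enrichment score of a set is the signed maximum deviation of the weighted
Kolmogorov–Smirnov running sum: hits increment by $|t|^p$ (normalized),
misses decrement by $1/(N - N_h)$, with weight $p = 1$ by default. The
null is gene-label permutation — set membership reassigned to random
positions — because with three replicates per group phenotype permutation
admits only ten distinct relabelings;
$p = (1 + \#\{|ES^\ast| \ge |ES|\})/(1 + n_{perm})$, the normalized score
divides by the mean $|ES^\ast|$ of matching sign, and q-values are
Benjamini–Hochberg across sets. An exact tie between the positive and
negative running-sum extremes resolves to the positive branch. Gene sets
come from user-supplied GMT files; no pathway collection is bundled because
the original collection and its vintage are unknown, so the synthetic sets
carry descriptive names (`cholesterol_synthesis_like`, …) and are labelled
synthetic throughout.

## What the synthetic generator does and does not emulate

`gen_dose_response` draws $y = f(x)\,e^{\varepsilon}$,
$\varepsilon \sim N(0, sd^2)$, on a two-fold dose grid (six points plus a
zero-dose control, top dose 100 µg/mL by default) with three replicates and
log-scale sd 0.05 — the multiplicative noise matches the fitting
likelihood, making recovery tests well-posed. `gen_elisa_plate` produces an
8-point two-fold standard series, duplicate blanks and four wells per
sample condition from a true 5PL curve plus additive OD noise.
`gen_expression` builds the 8-condition × 3-replicate design (wildtype
cells under control/star/sphere/rod exposures; ASC- and NLRP3-deficient
cells under control/rod), with per-gene baselines $N(8, 2^2)$ on the log2
scale, within-group sd 0.25, 1–3 probes per gene, fabricated quality flags
at configurable failure rates, spiked DEGs at log2FC ±2, and coherent
shifts of the synthetic gene sets chosen once so the headline qualitative
pattern is reproducible in silico: a rod-like condition with falling
viability and rising IL-1β, flat star/sphere viability, and rod-specific
downward shifts of the cholesterol-synthesis-like and
oxidative-phosphorylation-like sets. All generators are deterministic per
seed and write their ground truth beside the data.

What passing recovery tests on these data shows is that the estimators are
correct under their own assumptions. Real plates and arrays additionally
carry dye bias, spatial gradients, batch effects, heteroscedastic
low-intensity noise and annotation drift, none of which the generator
emulates — so the tests validate the statistical machinery, not robustness
to scanner-level artefacts.

## Problem sizes used by the tests

The test suite keeps simulation sizes modest: 100 seeds for BMD recovery
and interval coverage, 200 seeds for the null calibration of the DEG
selection at 1,000 genes per simulation (the significant fraction is a
per-test property, so it does not depend on the universe size), five
fixtures for the profile-bound oracle, exhaustive enumeration of all gene
subsets for universes up to 12 genes, and a demonstration pipeline at 600
genes with 200 permutations. The analysis drivers under `analysis/` run the
full-scale configuration (10,246 genes, 24 samples, 1,000 permutations,
three pooled experiments per dose-response endpoint).
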
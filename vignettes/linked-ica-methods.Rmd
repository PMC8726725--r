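---
title: "Linked ICA of brain networks and gut microbiota: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked ICA of brain networks and gut microbiota: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gblica)
```

## The problem

Gut–brain studies increasingly collect, from the same subjects, resting-state
fMRI and 16S gut-microbiome profiles. Mass-univariate correlation of every
voxel against every genus squanders power and ignores that both data types
are themselves highly structured. Linked independent component analysis
(LICA) instead factorizes all modalities *jointly*: every modality gets its
own spatial/feature patterns, but all factorizations share one
subject-loading matrix, so a component is, by construction, a pattern of
coupled variation — subjects who express a component strongly show both its
connectivity pattern and its abundance pattern.

`gblica` implements that workflow end to end: dual regression of template
resting-state networks to obtain subject-specific network z-maps; genus-level
prevalence filtering and relative-abundance normalization of a count table;
the joint factorization; and the component-selection and quality-control
rules used to read the result. A synthetic-cohort generator with known ground
truth backs every stage's validation.

## Model

For modality $k$ (a brain network's subject-map stack, or the genus
composition table), arranged as a feature $\times$ subject matrix $X_k$ and
standardized as described below,

$$X_k \approx S_k \,\mathrm{diag}(\lambda_k)\, H, \qquad k = 1, \dots, K,$$

with

* $H$ — the shared $C \times R$ subject-loading ("mixing") matrix, rows
  unit-norm; entry $H_{c,r}$ is subject $r$'s expression of component $c$;
* $S_k$ — feature $\times C$ source maps, columns unit-norm (voxel patterns
  for brain modalities, genus-loading vectors for the microbiome);
* $\lambda_{k,c} \ge 0$ — the weight of component $c$ in modality $k$. With
  both factors unit-norm, $\lambda_{k,c}$ is the component's singular value
  in that modality and $\lambda_{k,c}^2$ its explained variance.

Noise is i.i.d. Gaussian with per-modality precision $\beta_k$. The
per-component modality contribution is
$P_{k,c} = \lambda_{k,c}^2 \big/ \sum_{k'} \lambda_{k',c}^2$, the quantity on
which the non-marginal ($>0.2$) selection rule operates.

What makes this ICA rather than a PCA-style factorization is the source
prior: each entry of $S_k$ (internally, of $W_k = S_k\,\mathrm{diag}(\lambda_k)$)
carries a two-component Gaussian mixture — a narrow spike at zero and a
wider slab — expressing that component maps are sparse. Gaussian likelihood
plus Gaussian priors would leave the factorization defined only up to
rotation; the non-Gaussian spike/slab prior picks one representation out of
that continuum, and it is also the mechanism of automatic relevance
determination (ARD): when a component explains nothing in a modality, the
EM-updated slab variance of that column collapses towards the spike and the
corresponding $\lambda_{k,c}$ is driven to zero, so components can drop out
of modalities they do not explain.

## Estimation

`fit_lica()` runs MAP block-coordinate descent on the penalized objective
(negative log-posterior) in the parameterization $W_k = S_k\,\mathrm{diag}(\lambda_k)$,
with a standard-normal prior on $H$ fixing the scale:

1. **Loading update** — closed-form ridge solve pooling all modalities,
   weighted by $\beta_k$.
2. **Source update** — per component, the partial-residual least-squares
   target is shrunk entry-wise by the spike/slab prior; the update evaluates
   a small candidate set (current value, least-squares value, spike- and
   slab-shrunk values) and keeps the per-entry minimizer. Because the
   current value is always a candidate, the step can never increase the
   objective.
3. **Slab variance** — one EM step per (modality, component); EM cannot
   increase the penalty at fixed weights. A floor of $10^{-3}$ (spike
   variance $10^{-4}$, slab prior probability 0.1 by default, all in
   standardized units) keeps the mixture proper.
4. **Noise precision** — closed form $\beta_k = N_k R / \mathrm{RSS}_k$,
   capped at $10^{12}$ so noiseless inputs remain numerically exact.

Two further move families address the rotation problem directly. Every 10
iterations, a Jacobi-style sweep over component pairs searches (a)
orthogonal rotations of the $W$ columns with the inverse rotation of the $H$
rows — these leave the reconstruction and the $H$ prior untouched, so the
sparsity penalty alone decides — and (b) shear moves
$W_c \leftarrow W_c - \alpha W_d$, $H_d \leftarrow H_d + \alpha H_c$, which
additionally trade $H$-prior mass and are what separate components whose
subject loadings are *correlated* (an oblique unmixing; true loadings have
no reason to be orthogonal). Convergence is only declared once a final
sweep finds no further improving pair move. All moves are accepted only if
they lower the objective, so the objective trace is monotone non-increasing
by construction — a property the test suite asserts at every iteration.

**Initialization and restarts.** The first start is the deterministic SVD of
the row-stacked standardized modalities. The spike/slab objective is
multimodal in the component rotation, and we observed cohorts (planted
components with near-equal singular values and correlated loadings) where
the SVD start converges to a rotationally mixed stationary point that the
pair sweeps cannot leave, while the well-separated solution has a clearly
lower objective. `fit_lica()` therefore runs two additional seeded
random starts by default (`n_restarts = 2`) and returns the run with the
lowest final objective. The whole procedure remains a deterministic function
of the data and the `seed` argument.

**Conventions.** Components are ordered by total explained variance
$\sum_k \lambda_{k,c}^2$ (descending); each loading row's largest-magnitude
entry is made positive (source columns flipped in compensation); source
columns and loading rows are unit-normalized with the scale carried by
$\lambda$. Convergence is declared when the relative objective change falls
below `tol` (default $10^{-6}$; `max_iter` default 1000), *and* a final
pair sweep finds no further improvement.

## Standardization and what "contribution" means

`standardize_modalities()` centers each feature across subjects and rescales
each modality globally to unit mean square. This puts a ~400-voxel network
stack and a ~30-genus composition table on a common footing: contribution
fractions compare explained *shares* of each modality's variance, not raw
sums of squares that would let the larger modality swamp the smaller by
size alone. Centers and scale factors are stored, and
`destandardize_modality()` / `reconstruct(..., destandardize = TRUE)` invert
the transform. A consequence worth remembering: planted weights in a
simulation must be rescaled by the same factors before being compared with
fitted $\lambda$ — the generator's truth is declared on the standardized
scale in all validation code here.

## Dual regression

Stage 1 regresses, at each timepoint, the volume jointly on all template
network maps (intercept absorbed by demeaning over voxels), yielding
network timecourses. Stage 2 variance-normalizes the timecourses and
regresses each voxel's demeaned time series jointly on all of them. The
default output converts each coefficient to $t = \beta/\mathrm{SE}$ and then
to a z-score by the exact $t \to z$ quantile transform at the residual
degrees of freedom ($T - K - 1$), matching the use of subject-specific
*z*-maps as the brain-side input; raw betas remain available
(`output = "beta"`). Both stages always condition on the *full* template
set; selecting networks of interest happens only when stacking outputs, so
a selected network's map is always estimated in the presence of the other
networks. Voxels with zero temporal variance in any subject are masked out
of every output stack and recorded in the mask slot.

On noiseless self-consistent inputs both stages invert the generative model
exactly (to numerical precision), and on pure-noise inputs the z-maps are
standard normal — both properties are asserted in the test suite.

## Microbiome preparation

`prepare_microbiome()` chains genus aggregation (taxa sharing a genus label
summed; taxa without a named genus pooled under their lowest named rank as
`unclassified_*`), prevalence filtering (keep genera detected — count
$> 0$ — in at least 30% of samples by default, a `>=` comparison evaluated
on the presence count so exact boundaries like 3/10 at 0.30 are kept), and
relative-abundance normalization (each count divided by its sample total).
The default order is filter-then-normalize, so retained genera sum to 1 per
sample; `order = "normalize-first"` computes proportions on the full genus
table and carries them through the filter without rescaling, for
sensitivity analyses of that choice. Whether abundances should be further
transformed (e.g. log-ratio) before factorization is deliberately left out:
the composition table enters the model as proportions, standardized like
every other modality.

## Component selection and quality control

* **Selection** (`select_components()`): a component is kept when its
  microbiome fraction exceeds 0.2 *and* the summed fraction over all brain
  networks exceeds 0.2. The brain side is read as a sum because joint
  components typically spread over several networks; per-network exceedance
  flags are emitted alongside so the stricter per-network reading stays
  inspectable.
* **Single-subject dominance** (`subject_dominance()`): the largest share of
  a component's loading energy carried by one subject,
  $\max_r H_{c,r}^2 / \sum_r H_{c,r}^2 \in [1/R, 1]$. A component whose
  dominance exceeds 0.5 — one subject carrying more energy than everyone
  else combined — is flagged as a likely artifact. The 0.5 default is this
  package's choice of a natural majority threshold; it is a parameter.
* **Constant maps** (`flag_constant_map()`): a source column whose variance
  across voxels is below $10^{-8}$ times the modality's mean column
  variance is equal-valued to numerical precision and uninterpretable;
  such components are flagged and excluded from loading thresholding. The
  threshold is deliberately strict: it detects the degenerate model output,
  not merely a spatially smooth map.
* **Display thresholding** (`threshold_loadings()`): source columns are
  standardized within-column ("standardized loading z" — an empirical
  z-unit, not a posterior statistic) and reported two-sided at $|z| > 3$
  for brain maps and $|z| > 2.3$ for the sparser genus loadings, with signs
  (positive = more abundant / stronger connectivity with higher component
  expression).

## The synthetic-data generator

`make_joint_dataset()` builds cohorts in which every downstream stage has a
planted, recoverable answer. Loading rows are standard normal (unit
normalized) by default — the subject-level distribution is not prescribed by
the study design this emulates, and a caller can plant specific loadings
(e.g. a single-subject artifact row) via `loadings`. Sources are sparse:
a `sparsity` fraction (default 0.1) of standard-normal entries survives,
columns renormalized — the non-Gaussianity that makes the planted
factorization identifiable. Each modality matrix is
$S_k \mathrm{diag}(\lambda_k) H$ plus Gaussian noise, features centered.

Defaults define the simulated study conditions: 40 subjects, 2 networks on
$6 \times 6 \times 6$ voxel grids, 30 genera, 3 components, noise sd 0.1.
The default weight matrix alternates 10/7 across components for brain rows
and 3/2.1 for the microbiome row: with unit-norm factors $\lambda$ is the
modality singular value, so brain weights ~10 against noise sd 0.1 on a
$216 \times 40$ matrix give a per-entry signal-to-noise variance ratio
around 3 — clearly visible but noisy maps — while microbiome weights ~3
correspond to log-abundance perturbations around 0.3, i.e. fold changes of
roughly 1.3, a realistic effect size for gut genera.

The microbiome modality doubles as a composition generator: a baseline
log-abundance profile (normal, sd 1.5 — spanning the several orders of
magnitude typical of gut genera) plus the planted latent signal is passed
through a softmax per subject, yielding simplex-valued relative abundances,
optionally sampled into counts at fixed depth (multinomial). The `modalities`
list carries the *linear* latent matrices for all modalities (so noiseless
cohorts are exactly rank-$C$ and model-based validation is exact), while
`composition`/`counts` carry the nonlinear observable the microbiome
pipeline consumes. With `timepoints` set, per-subject fMRI is generated as
(template + subject deviation) maps times random timecourses plus noise,
on a concatenated grid with one block per network, so dual regression can
be exercised end to end and is exactly invertible at zero noise.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: hemodynamic autocorrelation and spatially
correlated fMRI noise, registration error, compositional covariance beyond
the planted factors (no phylogenetic structure), sequencing depth variation,
and any nonlinearity in the brain–microbiome coupling beyond the softmax on
the microbiome side.

## Numerical choices and degenerate inputs

* Spike variance $10^{-4}$, slab floor $10^{-3}$, slab probability 0.1,
  noise-precision cap $10^{12}$ — all on the standardized scale.
* Rank-deficient regression designs error out naming the collinear pair;
  zero-variance modalities, zero-total samples, and zero loading rows are
  hard errors naming the offender.
* An all-zero $\lambda$ column yields a uniform contribution column flagged
  `degenerate` rather than 0/0.
* Ties in component ordering are resolved by the pre-order index (stable);
  sign is fixed by the largest-magnitude loading entry.
* `reconstruct()` with an empty component subset returns the zero matrix by
  definition, supporting variance bookkeeping.

## Problem sizes used in validation

The shipped validation suite runs cohorts of 20–40 subjects, 1–2 networks on
$4^3$–$6^3$ grids, 15–30 genera and 2–3 components, with 20-seed repetition
suites for the QC rules and recovery-vs-noise curves; these sizes give
stable statistics for every property checked while keeping a full run in the
minutes range. The factorization itself has no size assumptions beyond
`n_components <= n_subjects`; the 10-component default mirrors the forced
model order used at the 58-subject scale of the motivating study design.

## Known limitations

* The fit is MAP, not full variational Bayes: no posterior uncertainty on
  loadings or sources is produced, and the loading z-units in reports are
  within-column standardizations, flagged as such.
* Model order is user-set; no automatic order selection.
* Subjects missing a modality are not supported — alignment is by id
  intersection with hard failure on mismatch, so cohort bookkeeping stays
  auditable.
* Contribution fractions depend on the unit-mean-square standardization
  convention; alternative weightings (e.g. per-feature) would change the
  selection arithmetic and are not implemented.

## A worked miniature

```{r example, eval = FALSE}
co <- make_joint_dataset(seed = 1)           # 40 subjects, 2 networks, 30 genera
fit <- fit_lica(co$modalities, n_components = 3, seed = 1)
P <- contribution_fractions(fit)
reports <- component_reports(fit)
round(P, 2)
vapply(reports, function(r) r$selected, logical(1))
```

Fitting the cohort's modalities and comparing `fit$H` against
`co$truth$H_true` (after greedy matching by absolute correlation) is the
package's central recovery check; `scripts/acceptance.R` reruns it from
scratch, together with the dual-regression oracles, the microbiome
brute-force checks, the QC repetition suites and the pipeline determinism
check, and writes the resulting numbers as JSON.
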
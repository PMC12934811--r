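---
title: "Methods: harmonized modeling of multi-study drug screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized modeling of multi-study drug screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, estimators and design choices behind
`panscreen`, in the spirit of a statistical supplement: what is assumed,
what is tunable, and what the synthetic validation does and does not show.

## 1. Data model

Viability records are long-format rows (study, sample, drug, concentration
in µM, viability as fraction of control). Validation enforces positive
concentrations and viabilities in [0, 2]: values in (1, 2] are legitimate
over-control growth and are retained in the data, while the *model mean* is
constrained to (0, 1] — observation noise absorbs the overshoot. A *curve*
is the set of records sharing (study, sample, drug); replicates at a dose
are kept as separate records (the likelihood handles replicate noise) and
auto-indexed when no replicate column is supplied.

All concentrations are handled internally in log10(µM). Each drug receives
a K-point dose grid (default K = 10) uniform in log10 over its observed
range pooled across studies. Single-concentration libraries are real and
common; a drug observed at a single concentration c gets a grid spanning
log10(c) ± 1 (the `single_dose_span`), wide enough for the factorization to
position its curve while anchored at the measured dose. K, the placement
rule and the span are configuration, not constants, because no canonical
convention exists for them.

## 2. Drug-identity harmonization

Raw names are normalized (lowercase; whitespace/punctuation collapsed; a
configurable trailing salt/formulation suffix list, shipped as an editable
text resource, is stripped). An undirected alias graph links normalized
names via exact matches across studies and a curated synonym table; drug
identities are the connected components, iterated to a fixpoint because a
merge can expose a new curated link. Components containing two or more
distinct curated canonical names are split back along curated lines and
flagged for review — when curation disagrees, refusing to merge is safer
than guessing. The procedure is idempotent and independent of study input
order (both properties are tested). Structure-based identity resolution
(SMILES/InChI) is deliberately out of scope.

## 3. The dose-response model

For sample $i$ and drug $j$ with grid points $k = 1..K$:

$$m_{ij0} = 1,\qquad m_{ijk} = m_{ij,k-1}\,\sigma(u_j^{(k)} \cdot v_i),$$

with $\sigma$ the logistic function, $v_i \in \mathbb{R}^d$ (default
$d = 32$) and per-grid-point drug embeddings $u_j^{(k)} \in \mathbb{R}^d$.
The inner product is interpreted as the log-odds of the *retention
fraction* $m_k / m_{k-1}$, which guarantees every latent curve is monotone
non-increasing and in (0, 1] — the interpretation we committed to so that
imputations are monotone-down by construction rather than by post-hoc
correction. Off-grid queries interpolate linearly in log10 concentration;
beyond the grid ends the curve extrapolates flat, because the data carry no
information there and flat extension preserves monotonicity and range.

**Inference.** Mean-field Gaussian posteriors on every embedding
coordinate, N(0, τ²) priors (τ = 1), a Gaussian likelihood with a learned
per-study noise standard deviation (log-parameterized, initialized at
0.15), and full-batch Adam on the negative evidence lower bound with one
reparameterized draw per step. The Gaussian likelihood is the simplest
choice that accommodates viabilities above the model mean. Uncertainty is
propagated by S posterior draws (default 50); every draw's curve is
individually monotone, and pointwise 5%/95% quantiles give a central 90%
band. Markov chain Monte Carlo would be a drop-in alternative for the same
model but is not the default on tractability grounds.

**Contrastive regularization.** Two supervised-contrastive penalties act on
posterior means: samples grouped by primary tissue site, and drugs —
represented by the concatenation of their K grid embeddings — grouped by
first-listed mechanism. Per anchor the penalty is
$-\log\left(\sum_{p \in P} e^{s_p/T} / \sum_{b \neq a} e^{s_b/T}\right)$
on cosine similarities (temperature T = 0.5), averaged over anchors;
unlabeled entities are excluded from the penalty but not from the
likelihood. Because the penalty is a per-anchor average while the
likelihood is a sum over N observations, the penalty enters the objective
multiplied by λ·N — this makes λ (default 0.1 for both penalties)
meaningful across dataset sizes. The analytic gradient of the penalty is
implemented directly and verified against finite differences in the test
suite.

**Cold-start embedding.** `embed_new_sample()` optimizes only a new
sample's posterior against a pilot screen's likelihood with all drug
parameters frozen at their posterior means — the backbone of the
virtual-screen power analysis.

## 4. Curve summaries and de-batched z-scores

AUC is the trapezoid integral of viability over log10 concentration
normalized by the range width (1 = no effect); it is computed on the
model-imputed grid for *all* curves, observed and imputed alike, so the two
kinds of summary are commensurable, with provenance recorded per cell. IC50
is the log-linear interpolated first crossing of viability 0.5, censored
`above_max` / `below_min` at the grid boundaries when no crossing exists.

The empirical null for one sample's AUC histogram is median/MAD (scaled by
1.4826), optionally refined by one pass over values with provisional
|z| ≤ 2.5 — a robust location/scale pair that ignores the outlying drugs
the sample is genuinely sensitive or resistant to. The published lineage
for this step is empirical-Bayes without printed formulas; median/MAD with
a trimming toggle is our committed estimator. Z-scores are
$(\mu_0 - \mathrm{AUC})/\sigma_0$, so **positive z = more cytotoxic than
the sample's typical drug**; the sign convention follows the observation
that broadly cytotoxic classes (e.g. proteasome inhibitors) should sit at
the top. Nulls are fit per (study, sample); a sample screened in two
studies gets two nulls, since batch effects are study-level. Global
(pooled) z-scoring is provided only as the comparison arm that
demonstrably fails to remove study shifts.

## 5. Differential analyses

- *Tissue-vs-rest*: primary samples only; per (tissue, drug) Welch t-test
  of z against all other tissues pooled, BH across all pairs, default FDR
  0.1. Welch is used wherever an unqualified "t-test" is called for,
  because group sizes are always unequal. Z-scores are already de-batched,
  so tissues are pooled across studies without further stratification.
- *Metastatic-vs-primary*: per (disease, drug) sign of the AUC difference
  with a one-sided binomial test for metastatic resistance; a two-sided
  Mann-Whitney restricted to standard-of-care drugs; per target-group z
  differences with seeded percentile bootstrap CIs (default 1,000
  resamples) and average-linkage clustering on the Pearson-correlation
  distance of disease-wise difference vectors. Diseases with fewer than 3
  metastatic samples are excluded (the minimum group size of 3 applies
  package-wide and is configurable).
- *Cell-line-vs-ex-vivo*: per (disease, status, class) mean z difference
  with a seeded permutation test (two-sided, add-one p-value), BH across
  strata, per-class cross-disease aggregation by Fisher's method. The
  paired cycling-vs-signaling comparison ranks each drug's z within its
  sample's own panel, divides by panel size ("normalized ranking" — the
  definition is ours, chosen for invariance to panel composition), averages
  within drug group, and compares the per-disease modality deviations by
  two-tailed paired t-test.
- *k-NN analyses* on embeddings use Euclidean distance. Disease purity is
  majority-vote over k = 5 neighbors (ties break toward the sample's own
  label; an any-match rule is available as an option), tested per label
  against prevalence by binomial test; mutation enrichment uses the nearest
  neighbor and Fisher exact tests; the TMB analysis reports Pearson r of
  own-vs-neighbor TMB with a percentile bootstrap CI.

## 6. The few-shot foundation model

Tokens concatenate three sub-embeddings (drug dictionary, Fourier dose,
Fourier viability; 3 × 128 = 384 at full scale). Fourier features use 32
(full) or 16 (desk) learnable frequencies initialized log-spaced over
[0.2, 8] cycles per unit — covering variation from ~0.1 to several log10
units — plus learnable phases and a shared linear projection. Query tokens
substitute a learned placeholder for the unknown viability. Out-of-
vocabulary drugs map to one reserved trainable embedding with a warning.

Architecture choices the source material leaves open, committed here:

- **No positional encodings.** Context and query are sets; permutation
  invariance becomes a testable property (asserted to 1e-6).
- **Cross-attention as a masked joint stack.** Each block runs
  self-attention over the concatenated [context ‖ query] sequence with a
  mask: context tokens attend only to context; query tokens attend to
  context and themselves. One stack, bit-exactly specified, equivalent in
  expressive role to two-stream cross-attention.
- **Objective**: mean-squared error on query viabilities, episodic
  training — sample one biological sample, split its measurements into a
  context (size uniform on `context_range`, default 5–50) and a query set.
- **Sample embedding** = mean-pooled final-block context representations.
- **Desk preset**: 2 blocks, hidden 96, 4 heads, intermediate 128 — the
  architecture scaled to interactive CPU use; the full-scale preset keeps
  8/384/8/512.

Forward and backward passes (layernorm, multi-head attention with the mask,
GELU feed-forward, Fourier and dictionary embeddings) are implemented
directly in R; gradient correctness is exercised by the training tests
(loss decrease, seed determinism) and the contrastive-gradient
finite-difference check covers the shared pattern. Fine-tuning (FM++)
copies the model and runs a few low-learning-rate epochs on the new
few-shot records only; zero epochs is the identity.

Probes are deliberately plain: logistic regression (AUROC, stratified
5-fold CV) for mutations — embeddings are PCA-compressed to 10 components
before the probe to keep small-n logistic fits stable — ridge regression
with inner-CV regularization (`glmnet`, α = 0) for pathway activities, and
one-sided Mann-Whitney tests per few-shot repeat combined by Fisher's
method for joint consistency. Pathway activity is the first principal
component of library-size-normalized, log1p, per-gene standardized member
genes, sign-oriented so the mean loading is positive.

## 7. The synthetic generator

The generator emulates the structure the pipeline must survive: 6 studies ×
30 samples by default, 120 drugs across 10 mechanism classes, 8 tissue
sites (one disease per tissue), 50% drug panels drawn per study, 5-dose
grids with study 6 single-dose, Hill-type ground truth (top fixed at 1,
bottoms in [0, 0.3], slopes in [0.8, 2]), ~30% metastatic samples with a
+0.4 log10-IC50 resistance shift, affine per-study batch effects on the
viability scale (offset and log-scale sd 0.08 — study-level assay
differences act on the readout, hence viability-scale), and measurement
noise sd 0.07, all values chosen once as representative of normalized
ex vivo screens. Planted tissue-by-mechanism effects are an explicit table
(default: three cells at ∓1.5 log10 IC50 with zero background) rather than
random draws, so "the set of planted hits" is well-defined for sensitivity
calculations; a background-sd knob exists for diffuse-effect scenarios.
Mutation effects couple two genes to two mechanism classes, and the omics
module ties the first of them to a pathway activity, giving the
mutation → expression → drug-response chain the probes are tested against.

What passing tests on this generator shows: the estimators recover known
structure through realistic missingness, batch effects and noise, at the
configured effect sizes. What it does not show: performance under real
screens' heavy-tailed noise, plate artifacts, mechanism-correlated panel
design, or annotation errors — the generator's effects are clean and its
noise Gaussian by design.

## 8. Numerical choices and problem sizes

- Curve interpolation clamps beyond grid ends; IC50 ties at exactly 0.5
  return the grid point; ranking ties in the power analysis break by lower
  AUC then lexicographic drug id.
- Permutation and bootstrap p-values use add-one floors
  ((1 + #exceedances)/(B + 1)); all resampling is seeded.
- The empirical-null trim threshold is |z| ≤ 2.5; degenerate spreads
  (MAD = 0) are an error rather than silently producing infinite z.
- Percentages derived from published incidence counts are reported at the
  source tables' printed precision (truncated to one decimal), matching how
  those tables print shares.
- Default problem sizes in the test suite and acceptance script — chosen as
  the package's validation scale — are the generator defaults above, with
  the dose-response model run at 300 optimizer iterations for the
  default-config fits (the `drm_config()` default is 600, which the
  noise-free recovery tests use), 30 posterior draws for banded
  imputations, and the desk-preset transformer at 400 steps. The
  whole-suite runtime is minutes on one CPU.

## 9. Known limitations

- Variational posteriors understate tail uncertainty; the 90% bands are
  calibrated in rank (wider band ⇒ larger expected error — this is what the
  tests assert) rather than guaranteed coverage.
- The pure-R transformer is sized for desk-scale experiments; the
  full-scale preset is faithful but slow without compiled backends.
- The alias graph resolves only name-level identity; distinct salts merged
  by the suffix list are treated as the same compound.
- Single-dose libraries borrow their curve shape entirely from the
  factorization; their IC50s inherit model, not measurement, uncertainty.
- The CLI covers the simulate/fit/impute/zscore path; the analysis
  functions are the R interface by design.
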
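---
title: "Methods: dynamics-based and latent-factor genomic prediction of longitudinal multi-trait phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamics-based and latent-factor genomic prediction of longitudinal multi-trait phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput phenotyping yields, for each genotype in a population,
dozens of image-derived traits measured at daily resolution across
development. Two families of genomic prediction (GP) can exploit such
data: *direct* (static) methods that treat every trait–time-point pair as
a column of a large multi-variate model, and *dynamics-based* methods
that first learn, per genotype, a linear operator governing how the
phenome state advances one day, and then predict that operator — rather
than the phenotypes — from genome-wide markers. `longigp` implements
both families behind a common cross-validation and evaluation harness,
together with a synthetic data generator that realizes exactly the
generative model the dynamics-based method assumes, so that every claim
the package makes can be checked against a known truth.

## The dynamics model and its Schur decomposition

For one genotype, let $x_t \in \mathbb{R}^p$ hold the $p$ trait values at
time point $t$. The working model is a linear time-invariant system
$x_{t+1} = A x_t$ with $A \in \mathbb{R}^{p\times p}$. Stacking
$X_1 = [x_1 \dots x_{T-1}]$ and $X_2 = [x_2 \dots x_T]$, the least-squares
estimate is $A = X_2 X_1^{\dagger}$ (`exact_dmd()`), which has $p^2$ free
entries — too many to predict from markers one at a time.

The rank-reduced variant (`schur_dmd()`) works in the leading $r$
principal directions of $X_1 = U \Sigma V^\top$:

$$\tilde A = U_r^\top X_2 V_r \Sigma_r^{-1}, \qquad
  \tilde A = Q R Q^\top \ \text{(real Schur)}, \qquad
  \Phi = X_2 V_r \Sigma_r^{-1} Q, \qquad
  A_r = \Phi R \Phi^{\dagger}.$$

$R$ is real quasi-upper-triangular ($2\times 2$ diagonal blocks carry
complex-conjugate eigenvalue pairs, so all quantities stay real for real
data), and the operator is rebuilt from only $r^2 + pr$ numbers — the
entries of $R$ and $\Phi$. Pooled across genotypes, these entries are
*pseudo-traits*: ordinary quantitative traits that a GP model can
predict for unphenotyped genotypes, after which `reconstruct_operator()`
and `propagate()` turn the predicted operator into trait trajectories,
either *recursively* (predictions fed forward from the initial state) or
*iteratively* (each step seeded by the observed previous state).

The quasi-triangular structure guarantees a minimum number of zero
entries in $R$: $r(r-2)/2$ for even $r$ and $(r-1)^2/2$ for odd $r$
(`guaranteed_zero_count()`); at the default $r = 2$ no zeros are
guaranteed, and the sub-diagonal entry is zero exactly when the two
eigenvalues are real.

### Conventions that make pseudo-traits comparable across genotypes

SVD and Schur factors are only defined up to signs and ordering, and a
GP model regressing, say, $\Phi_{11}$ on markers across genotypes is
ill-posed unless every genotype's decomposition uses the same
convention. `longigp` fixes, deterministically:

* each column of $U$ (and of $Q$) is flipped so its largest-magnitude
  entry is positive, with $V$ (and $R \mapsto DRD$) adjusted accordingly;
* Schur eigenvalue blocks are sorted by decreasing modulus, using
  orthogonal adjacent-block swaps (the Sylvester-equation construction);
* after extraction, each mode column of $\Phi$ is sign-aligned against
  the population-mean mode (`extract_pseudotraits()`); mode *order* is
  already pinned by the modulus sorting.

Pseudo-trait columns that are constant across the population (for
example the structurally zero sub-diagonal of $R$ when all genotypes
have real eigenvalues) are flagged and excluded from GP fitting, and
re-inserted as constants when operators are reassembled.

### Measurement gaps

The time grid has a two-day dark period after every fifth measurement
day (a 7-day cycle of 5 measured + 2 unmeasured days), so the
transition across a gap spans three modeled days. Training excludes
gap-straddling transitions (`build_shifted_pair()`), keeping every
retained column pair a single-day interval; at prediction time one
application of the operator models one day, and gaps are bridged by
applying it once per elapsed day (`propagate(elapsed = ...)`). Whether
the original analysis emitted post-gap predictions in iterative mode is
not specified anywhere we could find; this package emits them, seeded by
the last available state, and evaluates them like any other time point.

## Genomic prediction cores

**Ridge-regression BLUP** (`fit_rrblup()`): markers are random effects
with common variance; the variance ratio $\lambda = \sigma_e^2 /
\sigma_u^2$ is estimated by restricted maximum likelihood through the
eigendecomposition of the marker kernel $WW^\top$ (centered dosages),
optimizing the profiled restricted likelihood over $\log\lambda \in
[-12, 12]$ to a $10^{-9}$ tolerance. **GBLUP** (`fit_gblup()`) is the
same mixed model with a genomic relationship matrix; with VanRaden's
method-1 GRM built from the identical markers (`vanraden_grm()`) the two
give equal predictions, an identity the test suite asserts to $10^{-6}$.

**Latent-factor multi-trait GP** (`fit_factor_mtgp()`): the trait matrix
is decomposed as $Y = \mathbf{1}\beta + F\Lambda + E$ with $k =
\max(1, \min(\lfloor n_{\text{train}}/4\rfloor, \lfloor t/2\rfloor))$
factors (`choose_k()`; we read the published rule's two arguments as
training-genotype count and model-column count, the only reading
consistent with the factorization's dimensions). Scores and loadings are
obtained by SVD initialisation plus alternating least squares; updates
that would increase the training reconstruction error are rejected, so
the error trace is non-increasing by construction, and iteration stops
at a relative change below $10^{-8}$ or 500 sweeps. Each factor column
then gets an independent GRM mixed model (REML variance split + BLUP).
This is a deterministic approximation with the same two-level structure
and the same data usage as the Gibbs-sampled factor models used in the
field; it is *not* a reimplementation of any sampler, and posterior
uncertainty is out of scope.

Prediction for test lines uses the genomic BLUP of each factor (CV1).
When secondary traits are observed for test lines (CV2), the factor
scores are the Gaussian posterior combining that genomic prior — whose
spread is the per-line prediction error variance of the factor BLUP
plus the factor's residual variance — with the observed secondary
columns weighted by inverse residual variances. With the secondary
block withheld this reduces bit-for-bit to CV1, which is tested.

## Prediction scenarios

Over a shared plan of $n$ iterations of $k$-fold cross-validation
(`make_cv_plan()`, per-iteration seeds at fixed offsets from a master
seed, fold sizes within one of each other):

* **ST-STP**: one single-trait model per trait–time pair ($pT$ models).
* **CV1**: one factor model over all $pT$ columns, genomic data only.
* **CV2.1**: as CV1, with the $p$ traits at $t=1$ observed for test
  lines as secondary traits; $p(T-1)$ focal columns.
* **CV2.2**: per transition $t \to t+1$, a factor model over $2p$
  columns with the time-$t$ block observed for test lines; $T-1$ models
  per split.
* **dynamicGP** (`run_dynamicgp()`): pseudo-traits of training lines
  (each derived solely from that line's own phenotypes) predicted for
  test lines — one ridge model per active pseudo-trait column, or $r+1$
  factor models (one for the $R$ entries, one per $\Phi$ mode);
  optionally the $t=1$ trait block joins as secondary traits
  (`include_tp1`), legitimate because the initial state is already an
  input of the propagation. Operators are reassembled and propagated
  from the true $x_1$.
* **Forecasting (CV3)** (`run_forecast()`): decompositions and GP fits
  use only time points $1..s$ (default $s=20$); propagation starts from
  the observed state at $s$ and covers $s+1..T$. Genotypes are seen and
  time points unseen, so the GP step fits on all lines and predicts
  in-sample by default (a plan adds genotype hold-out). In iterative
  mode the observed states at forecast horizons seed each step — an
  evaluation-only availability, which is the only reading under which
  iterative forecast accuracies can be reported at all. The static
  configurations are rejected with an explanatory error: without a
  dynamical model they could only repeat the last training time point.

Every orchestrator can log, per model fit, exactly which test-line
phenotype cells entered it (`audit_start()` / `audit_leakage()`); the
only allowed exposures are the documented secondary blocks ($t=1$, or
the preceding time point in CV2.2), and the acceptance suite asserts
zero violations across all seven scenarios.

## Accuracy assessment

*Snapshot* accuracy is the Pearson correlation (and MSE) between
predicted and true values across the test genotypes of a fold, per
trait–time cell, averaged with equal weight per fold and iteration
(whether the original analysis weighted folds by size is unstated; equal
weights are used). *Longitudinal* accuracy is the correlation and
untransformed MSE across the predicted time grid per genotype–trait
series and iteration; the initial time point is skipped by default for
parity across scenarios. Significance uses
$\mathrm{PCC}_{\text{thr}} = t_{\text{crit}} / \sqrt{t_{\text{crit}}^2 + n - 2}$
with the two-sided critical $t$ at a Bonferroni-corrected $\alpha$; the
family is the full count of evaluated series per scenario (traits
$\times$ genotypes $\times$ iterations). Undefined correlations
(constant series — recursive dynamicGP can produce them) count in
denominators, never in numerators, and negative significance is tracked
separately.

*Trajectory characteristics*: total and quadratic variation and the
coefficient of variation on the raw mean trajectory; RMS roughness and
kurtosis on the detrended series, where normalization divides by the
range only ($y/(\max - \min)$, no shift) and an OLS line on the index
$1..T$ is subtracted; mean second difference, the leading least-squares
parabola coefficient, and the mean chord deviation over all
$\binom{T}{3}$ index triples (an exhaustive $O(T^3)$ loop; at $T = 25$
that is 2,300 triples). Gap days are not expanded on the time axis: all
regressions use the index with unit spacing, mirroring the index-based
difference definitions. These are computed on the mean trajectory per
trait by default — a deliberate simplification, with a per-genotype
option — and correlated with per-trait accuracy summaries.

## The synthetic population

`simulate_genotypes()` builds a MAGIC-like population: 9 founder
haplotypes, markers on 10 chromosomes, each inbred line a recombinant
founder mosaic (about 2 crossovers per chromosome) with homozygous 0/2
dosages and a guaranteed minor allele frequency floor of 0.05. The
mosaic structure gives realistic linkage blocks; with independent
markers instead, the effective genome dimension at 5,000 markers would
cap RR-BLUP accuracy near 0.2 regardless of heritability, which is not
what a recombinant inbred population looks like.

`simulate_dynamic_phenome()` draws, per genotype, the free entries of an
upper-triangular $R_g$ (mean eigenvalues 0.99 and 0.92, genotype
deviations of sd 0.02) and of the mode matrix $\Phi_g$ (orthonormalized
population mean, deviations of sd 0.05), each as population mean +
marker-additive genetic value + environmental residual scaled to the
target heritability (default 0.9 per pseudo-trait, 50 QTL each). The
initial state is $x_1 = \Phi_g c_g$ with mildly heritable coordinates,
so each trajectory lies exactly in its genotype's mode space and
follows $x_{t+1} = A_g x_t$ with one operator application per elapsed
day (three across each gap). Should a draw produce a diverging
trajectory, the eigenvalues are rescaled into the unit disc and the
genotype flagged; with the default spectra this is rare. Observation
noise is off by default: the intended inputs are BLUP-like
genotype-level values whose replicate-level noise has already been
averaged out, so residual trait variation enters through the
pseudo-trait heritabilities instead.

What the generator does **not** emulate: replicated multi-environment
designs, real SPET marker spacing or linkage maps, selection, nonlinear
or age-dependent dynamics, and trait measurement error correlated
across traits. Tests passing on this generator therefore certify the
machinery (decomposition, conventions, GP cores, data flow, metrics),
not real-data performance.

### Normalization: an exact-recovery caveat

Trait scales are min-max normalized per trait, jointly across genotypes
and time points (the scope of the normalization was ambiguous in the
source material; per trait–time-point would destroy trajectory shape,
so per trait is used). For the *generator*, however, subtracting the
per-trait minimum adds a shared affine offset to every trajectory, and
an affine trajectory of a rank-$r$ system is exactly representable only
by a rank-$(r+1)$ linear operator: under the shift, rank-2 Schur-DMD
mis-reconstructs by about 0.08 on the unit scale and the extracted
pseudo-traits lose most of their heritability. This is a property of
the model class, not of the implementation. The generator therefore
offers three normalization modes — `"minmax"` (default, the study
condition), `"range"` (divide by the range only: unit-scale values,
trajectory shape preserved, and exact rank-$r$ linearity preserved,
the same scale-only normalization the trajectory metrics use), and
`"none"` — and the end-to-end generative-recovery checks run under
`"range"`, where the property they test is well-posed. One side effect
of the default worth knowing: under `"minmax"` the effective rank-3
data truncated at $r=2$ produce complex eigenvalue pairs in a subset of
genotypes, so the sub-diagonal $R$ entry is non-constant across the
population — the same mixed real/complex picture reported for real
data.

## Numerical choices

* Pseudoinverses via SVD with relative cutoff $10^{-12}\sigma_{\max}$.
* `schur_dmd()` refuses rank-deficient truncations
  ($\sigma_r \le 10^{-12}\sigma_1$) with a pointer to a smaller $r$.
* Representative selection in `mantel_select_traits()` breaks
  heritability ties by lexicographic trait id; the Mantel statistic is
  the Pearson correlation of lower-triangle Euclidean distances between
  genotype time-profiles (the conventional choice; the distance
  underlying the original analysis is unstated), and communities come
  from greedy modularity maximization on the unweighted thresholded
  graph.
* Missing dosages are mean-imputed per marker before the GRM; constant
  traits, zero-variance phenotypes, all-excluded transition sets and
  secondary blocks that are not a strict subset of model columns raise
  immediate argument errors.
* Degenerate factor scores (zero variance) get an infinite variance
  ratio and drop out of the genomic prior.

## Problem sizes used by tests and the acceptance script

Module tests run on populations of 10–100 lines with 30–250 markers and
panels of 2–7 traits over 6–25 time points; the end-to-end recovery
check and the acceptance script use the full study geometry (330 lines,
5,000 markers, 25 time points, rank 2) with 10 traits and one iteration
of 5-fold cross-validation, and the analysis drivers default to the
full 50-trait panel with two iterations. These sizes were chosen so a
complete run stays comfortably on a laptop while keeping every
population-level property (fold sizes of 66, heritability recovery
within $\pm 0.1$, accuracy decay over horizons) at the scale where it is
defined.

## Known limitations

* The latent-factor core is a deterministic approximation; its CV2
  weighting is the natural Gaussian posterior, which need not match any
  particular sampler's weighting.
* Pseudo-trait alignment relies on separated eigenvalue moduli; systems
  with nearly tied moduli can swap modes between genotypes, and no
  permutation-matching beyond the modulus ordering is attempted.
* All entries of $R$ are treated as free pseudo-traits even though
  complex-conjugate pairs make some of them functionally dependent; the
  redundancy is documented rather than modeled.
* Dynamics are strictly linear and time-invariant; variable-spacing and
  multi-resolution extensions are out of scope.
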
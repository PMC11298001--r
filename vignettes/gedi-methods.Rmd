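---
title: "Model and methods behind gedi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind gedi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`gedi` treats a multi-sample single-cell dataset as observations scattered
around sample-specific distortions of one shared low-dimensional manifold.
For cell $n$ from sample $i = i(n)$, the expected latent expression
profile is the affine image

$$\mu_n \;=\; o_r + \Delta o_i + (Z_r + \Delta Z_i)\,b_n + s_n 1_G,$$

where $o_r \in \mathbb{R}^G$ and $Z_r \in \mathbb{R}^{G\times K}$ define
the reference manifold (center and axes), $(\Delta o_i, \Delta Z_i)$ are
the per-sample translation and axis distortion, $b_n \in \mathbb{R}^K$ is
the cell's embedding, and $s_n$ is a cell intercept representing library
size. The latent profile is spherical Gaussian around $\mu_n$ with
variance $\sigma^2$. Three observation layers connect it to data:

* **gaussian** — the latent profile is observed directly (log-scale
  expression);
* **poisson** — UMI counts $m_{gn} \sim \mathrm{Pois}(e^{y_{gn}})$, i.e.
  a Poisson-log-normal layer; $y$ is the log rate and $s_n$ absorbs the
  sequencing depth;
* **binomial** — paired success/failure counts (exon
  inclusion/exclusion, spliced/unspliced) with
  $m_{1,gn} \sim \mathrm{B}(m_{gn}, S(y_{gn}))$; $y$ is the latent logit
  of the ratio (e.g. logit PSI).

Two optional hierarchy levels make the model *interpretable*:

* **sample covariates**: $\Delta o_i \sim \mathcal N(R_o h_i,\,
  \sigma^2 S_{\Delta o} I)$ and column-wise
  $\Delta z_{i,k} \sim \mathcal N(R_k h_i,\, \sigma^2 S_{\Delta Z} I)$,
  where $h_i \in \mathbb{R}^L$ are per-sample covariates. The matrices
  $R_o, R_k$ carry the *covariate response* of the manifold; the
  distortions keep their own variance around $R h_i$ (they are
  parameters, not deterministic functions of $H$).
* **gene-level priors**: $z_{r,k} \sim \mathcal N(C a_k,\,
  \sigma^2 S_Z I)$ with $a_k \sim \mathcal N(0, \sigma^2 S_A I)$, where
  $C$ is a $G \times P$ gene-set / regulon matrix. $A b_n$ is the
  projected activity of the $P$ sets in cell $n$, and $Z_r a_p^\top$ the
  expression-space gradient of set $p$'s activity.

Scale redundancy between axes and embeddings is resolved by the *gauge*:
every row of $B$ is a unit vector, with the norm carried by the axis
columns. Axes are kept mutually orthogonal, and optionally the columns of
$B$ are constrained to a hyperellipsoid with semi-axes $d$.

## Cluster-free differential expression

Because the decoder is affine in $h$, the derivative of $\mu_n$ with
respect to covariate $l$ is exact and per-cell:

$$v_n = R_o[,l] + \sum_k R_k[,l]\, b_{k,n}.$$

`vector_field()` returns this $G \times N$ field; its per-cell norms
locate the cell states with the largest expression shift, and
`field_group_summary()` collapses it to cluster-level mean DE vectors
comparable to pseudobulk log-fold-changes. `field_vs_gradient()` compares
the field with regulon-activity gradients by cosine similarity.

# Fitting

All parameter blocks given the latent profile are Gaussian, so every
conditional update is (ridge) least squares. In gaussian mode the fit is
plain block coordinate descent; in the count modes each sweep starts with
an E-step that replaces $y_{gn}$ by its posterior mean and variance given
the counts and the current decoder mean (expectation-maximization on the
penalized objective).

**E-step.** Both count layers give one-dimensional log-concave
posteriors. The mode is found by safeguarded Newton iteration; moments
are then computed by 32-node Gauss–Hermite quadrature centered at the
mode and scaled by the Laplace standard deviation. We deliberately do
*not* use the Laplace point approximation for the moments themselves: its
error in the posterior mean is $O(1/m)$ and stays above $10^{-3}$ even at
hundreds of counts, whereas the adaptive quadrature agrees with a
brute-force trapezoid oracle to better than $10^{-4}$ everywhere we test
(counts 0–500, prior means $\pm 5$, prior variances up to 4).

**Sweep structure.** Per sweep: E-step → $B$ → orthogonality →
$s$ (poisson only) → $o_r$ → $Z_r$ → $A$ → joint $(R_o, \Delta o)$ →
joint $(R_k, \Delta Z)$ → $\sigma^2$. The orthogonality basis change is
applied directly after the embedding update — it leaves every decoded
mean untouched but perturbs the axis priors, so all prior-bearing blocks
re-minimize before the objective is recorded. The unit-row gauge is
applied *once, after the final sweep* (again decode-invariant). Enforcing
it per sweep sets up a persistent scale limit-cycle — the $B$ update
re-absorbs the inverse of the axis-ridge shrinkage and the gauge then
rescales the axes against their own prior — which we measured leaking a
few $10^{-6}$ of relative objective per sweep. With the gauge deferred,
each sweep is pure penalized block coordinate ascent and the recorded
objective is monotone, which the test suite enforces at $10^{-6}$
relative slack.

**Joint covariate updates.** Updating $\Delta$-blocks and $R$-blocks one
at a time mixes extremely slowly when the distortion prior is tight: the
signal flows from data into $R$ with contraction $1/(1+S n)$ per sweep.
The fitting loop therefore estimates each $R$ from the *marginal* model
with its distortions integrated out (a gene-wise generalized ridge whose
curvature is shared across genes), then refreshes the distortions
conditional on $R$. This is exact joint minimization of the pair, so
monotonicity is preserved, and it converges in a handful of sweeps
instead of hundreds.

**Intercepts.** $s_n$ is a library-size term and is only updated in
poisson mode (initialized at $\log$ total counts). A free intercept in
the other modes would fold the ones vector into the axis span and destroy
the exact correspondence with PCA in the single-sample gaussian limit,
which we use as a closed-form check of the whole engine.

**$\sigma^2$.** A single pooled MAP update aggregates the data residuals
(plus E-step posterior variances) and all $\sigma^2$-scaled prior
quadratic forms, with degrees of freedom counted accordingly.

## Hyperparameters

All prior variances are ratios relative to $\sigma^2$. The defaults are
*gauge-consistent*: because rows of $B$ are unit vectors, an axis column
that contributes unit signal variance per matrix entry has norm
$\sqrt{NG}$, i.e. entries of $Z_r$, $\Delta Z_i$ and $R_k$ scale like
$\sqrt N$. Their ratios therefore carry a factor $N$
($S_Z = S_A = S_{R_k} = N$, $S_{\Delta Z} = N/Q$), which makes the
implied prior on the *reconstructed signal* $O(\sigma^2)$ and independent
of the number of cells. Translation-scale blocks are $O(1)$:
$S_{\Delta o} = 1/Q$, $S_{R_o} = 1$. With cell-count-independent $O(1)$
ratios on the axis blocks (an earlier iteration of this package), the
$Z$-prior quadratic form dominates the pooled $\sigma^2$ and inflates it
several-fold, wrecking the E-step; the $N$-scaled defaults remove this
failure mode. All ratios are exposed in `gedi_fit(hyper = ...)` and
recorded in the model archive.

## Constraints and identifiability

* Orthogonality is imposed on $Z_r$ as a decode-invariant change of basis
  ($Z_r \to Z_r T$, $\Delta Z_i \to \Delta Z_i T$, $B \to T^{-1}B$ with
  $T$ from symmetric (Löwdin) orthogonalization), applied once per sweep.
  Symmetric orthogonalization avoids the column-order dependence of
  Gram–Schmidt.
* The standalone `enforce_orthogonality()` additionally redistributes the
  original column norms, preserving the total Frobenius norm.
* After fitting, factors are put in canonical order: columns of $Z_r$
  sorted by decreasing norm, signs fixed so each column's
  largest-magnitude entry is positive. This makes factor order
  reproducible across runs.
* Ellipsoid option: the semi-axes $d$ are re-estimated each sweep from
  the per-factor spread of $B$ (scaled by $\sqrt K$ and rescaled so
  $\sum_k d_k^{-2} = N$ — the exact compatibility condition between unit
  row norms and the per-column ellipsoid; without it the two constraint
  sets need not intersect and alternating projection cannot converge).
  Note the two constraints are jointly satisfiable only under this kind
  of compatibility; e.g. $K=1$, $d=1$ is consistent only at $N=1$.
* A component of $\Delta o_i$ lying inside the axis span is exchangeable
  with a per-sample shift of embeddings; recovery tests therefore use
  $G \gg K$ where this leak is $O(K/G)$.

## Degenerate inputs and numerical choices

* $\sigma^2 = 0$ in the E-step returns the degenerate posterior
  ($E y = \mu$, $V y = 0$); paired entries with zero total count return
  the prior ($E y = \mu$, $V y = \sigma^2$) and are retained.
* Singular normal equations are ridge-stabilized ($10^{-10}$ relative);
  rank-deficient axis matrices are an error naming the dependent columns.
* Convergence: relative objective change below `tol` (default $10^{-6}$)
  or `max_sweeps` (default 200).
* Initialization is deterministic (truncated SVD of the
  mode-appropriate transform, SVD signs fixed by largest loading), so
  fits are reproducible; the `seed` argument is recorded for provenance
  and guards any future stochastic extension.

# The cohort simulator

`sim_params()` + `simulate_cohort()` generate a cohort-level benchmark
with known per-cell differential expression. Per sample $i$, each gene's
expression across $K_{arch}$ archetypes is drawn around
$X_g h_i + x'_g h_i 1$ with a low-rank-plus-diagonal covariance
$\Sigma_g = \tau^2 u_g u_g^\top + \omega^2 I$; each cell is a noisy
convex combination $w_n$ of its sample's archetypes
(Dirichlet-concentrated near the vertices), and UMI counts are drawn by a
per-cell multinomial over the softmax of the latent $\log_2$ profile at a
log-normal depth. The ground truth per-cell DE is the pure algebra
$\delta_{n,g} = w_n X_g$.

Deliberate choices, made once:

* **Baseline archetype profiles.** The covariate-only archetype mean
  would leave a world with no planted effects completely structureless,
  so a per-gene-per-archetype baseline matrix (SD 1.5 per gene, SD 1
  across archetypes) carries the cell-type structure. It contains no DE:
  $\delta = w_n X_g$ is unchanged, and `effect_fraction = 0` still
  implies $\delta \equiv 0$.
* **Effects.** 20% of genes carry effects by default; nonzero entries of
  $X_g$ are $\mathcal N(0, 1)$ in $\log_2$ units (the log base is 2, so
  DE thresholds like 0.3 are $\log_2$ fold changes). Covariate 1 is a
  balanced binary condition; further covariates are standard normal per
  sample.
* **Scales.** $\tau = 0.3$, $\omega = 0.2$ (sample-level archetype
  variability), cell-level SD uniform in $[0.2, 0.5]$, depths log-normal
  around 2000 — values a sequencing experiment of this size would
  plausibly show; at $G = 300$ they give a mean UMI count of ~7 per
  gene/cell.

The paired generator `simulate_paired()` reuses the archetype machinery
for a latent logit field (e.g. logit PSI) and draws per-event totals
$\mathrm{Pois}(\text{depth})$ with binomial successes. Its preset
`sim_params_paired()` emulates *subtle* splicing variation: wide
per-event baselines but cross-cell shifts of only ~0.2 logits and very
small unexplained cell noise. At depth 1–3 the binomial noise of a naive
count-ratio estimate (logit SD well above 1) then dominates the signal —
this is the regime in which naive PSI estimates are nearly uncorrelated
with the truth while the fitted manifold, pooling all events and cells,
still recovers it.

**What a green test does and does not establish.** The simulator plants
linear covariate responses on an archetype polytope with Gaussian
sample- and cell-level noise and multinomial counting — the same
structural assumptions the model makes (plus the softmax normalization
and discreteness it does not). Recovery on this world validates the
inference machinery, identifiability handling and the DE-vector algebra.
It does not establish performance under model misspecification: real
data have non-linear covariate responses, non-Gaussian sample effects,
ambient RNA, doublets, and zero-inflation beyond Poisson sampling, none
of which are emulated here (the `global_sd` stress knob adds only an
ambient-like shared artifact).

# Scope and limitations

* Linear (hyperplane/hyperellipsoid) decoders only; no nonlinear
  manifolds, no multi-modal mosaic integration, no GPU path.
* Desk-scale dense E-steps (up to a few million matrix entries); counts
  may be passed as sparse `Matrix` objects but are densified internally.
* No automatic selection of $K$ or hyperparameter cross-validation. In
  the benchmarks here, $K$ near the intrinsic dimension of the planted
  cell-state space recovers covariate responses best; factors beyond it
  mostly add noise to the field estimates.
* Statistical significance of DE vectors, embedding plots, and
  classifier training on sample features are out of scope; the features
  themselves (`sample_features()`, `residualize_features()`) are
  provided.
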
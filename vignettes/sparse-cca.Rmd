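---
title: "Sparse canonical correlation with exact support control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse canonical correlation with exact support control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two high-dimensional data blocks, $X_1 \in \mathbb{R}^{n\times p}$ and
$X_2 \in \mathbb{R}^{n\times q}$, are measured on the same $n$ samples —
typically two omics layers, or an omics layer against a panel of
phenotypes, with $p, q \gg n$. Canonical correlation analysis looks for
weight vectors $\alpha, \beta$ whose latent variables
$\gamma = X_1\alpha$ and $\zeta = X_2\beta$ are maximally correlated,

$$\rho \;=\; \frac{\alpha^{T} X_1^{T} X_2 \beta}
{\sqrt{\alpha^{T} X_1^{T} X_1 \alpha}\;
 \sqrt{\beta^{T} X_2^{T} X_2 \beta}}.$$

With $p > n$ there are infinitely many weight combinations achieving
perfect in-sample correlation, most of them noise. Lasso-type sparse CCA
controls this by a penalty whose parameter must be tuned, and the same
penalty can select different numbers of variables on different
(permuted) datasets, which both complicates interpretation and distorts
permutation nulls.

`softcca` instead fixes the *number of nonzero weights per block*,
$(p_\alpha, q_\beta)$, directly. Sparsity enters through a rank-based
soft-threshold inside an alternating NIPALS loop: after each
least-squares update the weight vector is reduced to its $p_\alpha$
(resp. $q_\beta$) largest-magnitude entries, each shrunk by the first
excluded magnitude. Every refit — on permuted data, on a training fold,
at a different sparsity level — selects exactly the same number of
variables, so statistics stay comparable across refits.

## The fitting loop

One component is estimated by alternating, starting from an initial
$\alpha^{(0)}$:

1. $\gamma \leftarrow X_1\alpha$, scaled to unit norm;
2. $\tilde\beta \leftarrow X_2^{T}\gamma$ (the least-squares update
   under the working assumption that the Gram matrix is the identity —
   collinearity is deliberately ignored, as in other NIPALS-type
   methods);
3. $\beta \leftarrow$ soft-threshold of $\tilde\beta$ at support size
   $q_\beta$;
4. symmetrically for $\zeta$ and $\alpha$ at support size $p_\alpha$;
5. stop when the correlation of the two latent variables changes by at
   most `tol`.

The threshold keeps the top-`keep` entries by magnitude and shrinks
survivors by $\lambda$, the $(\text{keep}+1)$-th largest magnitude,
preserving signs. Entries tied exactly at $\lambda$ are admitted in
ascending index order and shrink to zero, so a tie can leave the result
sparser than requested; this is deterministic and reported with a
warning. A vector thresholded to all zeros marks the component
*degenerate* (no signal at the requested sparsity) and truncates the
component sequence rather than erroring.

Later components are estimated on deflated matrices,
$X^{(k+1)} = (I_n - \gamma\gamma^{T}/\gamma^{T}\gamma)\,X^{(k)}$, each
block deflated by its own latent variable. In the unpenalized limit
this makes latent variables across components exactly orthogonal;
thresholding breaks that guarantee, which motivates the adjusted
explained-variance measure below.

In the unpenalized limit ($p_\alpha = p$, $q_\beta = q$) the loop is a
power iteration on $X_1^{T}X_2$ and converges to its leading singular
pair; the test suite uses this as an independent oracle.

### Numerical choices

* Convergence is declared when $|\rho^{(t)} - \rho^{(t-1)}| \le$ `tol`
  (default `1e-6`), capped at `max_iter = 500` iterations;
  non-convergence is flagged, never an error. The stopping rule watches
  the *correlation*, which settles roughly quadratically relative to the
  weight vectors — analyses that need the weights themselves to many
  digits (e.g. comparison against a singular-vector oracle) should
  tighten `tol` to `1e-12` or beyond.
* The correlation trace climbs but is not guaranteed monotone: isolated
  small dips occur when the iterate crosses a sub-dominant direction or
  the active support switches.
* Each component is sign-fixed so its largest-magnitude block-1 weight
  is positive; weight vectors are returned with unit Euclidean norm,
  latent variables with unit norm as stored in the component.
* Standardization uses the sample standard deviation (divisor $n-1$);
  constant columns are rejected by name.

### Initialization

`init` offers three schemes: `uniform_random` (i.i.d. uniform on
$(-1,1)$, seeded — the default), `uniform_constant` (all entries
$1/\sqrt{p}$), and `decomposition` (the leading right singular vector of
the current, possibly deflated, block-1 matrix).

The random default makes independent runs genuinely independent, which
is the honest choice for assessing stability. Its cost is that when two
components have similar strength, separate runs — different sparsity
levels of a path, different cross-validation folds — can estimate them
in *different orders*. For analyses that compare components across runs
(sparsity-path browsing, per-component out-of-sample correlations of a
multi-component fit) we recommend `init = "decomposition"`: it is
deterministic, data-driven, uses no held-out information when computed
on a training fold, and pins the estimation order to residual dominance
so the same component is compared with itself everywhere.

## Explained variance, adjusted

The cumulative proportion of explained variance after $k$ components is
$\mathrm{CPEV}(k) = \mathrm{tr}(G_k^{T}G_k)/\mathrm{tr}(X^{T}X)$, with
$G_k$ the first $k$ latent variables. Two conventions are possible.
With unit-norm latent variables the numerator is identically $k$ and
the measure is vacuous, so by default the package computes latents as
$X\alpha_k$ on the *original* matrix with unit-norm weight vectors
(`cpev_convention = "weights_unit"`); the literal unit-norm-latent
formula is kept as an option for comparability only.

Because sparse components need not be orthogonal, later components can
re-explain variance already counted. The adjusted measure discounts
component $k$ by $\prod_{i<k}\,(1 - |\mathrm{cor}(\gamma_i,\gamma_k)|)$:
a duplicated component contributes nothing, an uncorrelated one is
untouched. The adjustment uses absolute correlations, so it is invariant
to sign flips. We suggest reading the adjusted curve as a scree plot: a
plateau indicates that further components repeat old information.

## Out-of-sample correlation

The in-sample canonical correlation of a sparse fit grows with the
number of variables allowed in, whether or not they carry signal. The
package therefore evaluates components by their *out-of-sample*
correlation: 5-fold cross-validation by default (a single holdout split
is available), where each training fold is standardized, fitted up to
the component of interest (with deflation), and the frozen weights are
applied to the held-out rows standardized by the training centers and
scales. Fold weights are sign-aligned to the full-data fit before
averaging. Each fold must hold out at least 2 samples and train on at
least 3; degenerate training fits leave a missing fold, and the mean is
taken over the rest.

## Permutation testing

Each component's correlation is tested against the null of no
association between the blocks (and, for component $k$, between the
counterparts deflated by the observed first $k-1$ components). The rows
of block 2 are shuffled; one component is refitted at the *same*
$(p_\alpha, q_\beta)$; the statistic — out-of-sample correlation by
default, in-sample optionally — is recorded. The observed statistic is
computed by the identical routine on the unshuffled data, so observed
and null values are exchangeable under the null. Design details:

* one-sided (greater), with the $+1/+1$ convention
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$, so $p$ is never
  exactly zero and the floor is $1/(B+1)$;
* the fold assignment for the out-of-sample statistic is drawn once per
  tested component and shared by the observed statistic and every
  permutation, so all statistics are measured on identical splits;
  within a permutation, the row shuffle and the initialization derive
  from a per-permutation seed, making the test reproducible and
  order-independent;
* fold refits run on the (possibly deflated) matrices as-is: deflated
  columns are no longer standardizable, and a row permutation preserves
  column moments;
* multiplicity is handled by Bonferroni ($p_{\mathrm{bonf}} =
  \min(1, K\,p_{\mathrm{raw}})$) and, alternatively, by a max-statistic
  rule that compares each observed statistic against the $(1-\alpha)$
  quantile of the null draws of the component with the largest observed
  statistic. Both are reported; the package does not adjudicate between
  them.

## The synthetic-data generator

`scca_design()`/`scca_simulate()` implement a probabilistic-CCA
(latent Gaussian factor) generator: per component $k$ a shared latent
$z_k \sim N(0, \sigma_k^2)$ loads onto disjoint consecutive blocks of
features in each data block, plus i.i.d. $N(0, \sigma_\epsilon^2)$
noise. Defaults — $n = 100$, $p = 2500$, $q = 500$, three components
with support sizes $(80, 50, 30)$ and $(60, 40, 20)$, latent strengths
$(3, 2, 1.5)$, unit noise, loading magnitudes uniform on $(0.5, 1.5)$
with random signs — define the package's reference study conditions:
strong, well-separated, sparse signals at realistic multi-omics
dimensions. Strictly decreasing latent strengths make the component
order identifiable; `k_true = 0` gives the pure-noise null design used
for type-I-error calibration.

What the generator does *not* emulate: correlated noise, overlapping or
non-contiguous supports, heavy-tailed or discrete measurements, and
block-specific (non-shared) latent structure. Passing tests on this
generator demonstrate correct mechanics and calibration under the
factor model, not performance on any particular real dataset.

## What the test suite establishes, and at what sizes

The suite (and `scripts/acceptance.R`) works at the reference design
unless stated: the dense-limit singular-triple oracle runs on 25 random
$50\times20/15$ instances; type-I calibration uses 200 null replicates
at $n=50$, $p=200$, $q=100$ with $B=99$; the significance pattern and
adjusted-CPEV behaviour use ten replicates of the reference design with
$B=100$; nestedness and exact-sparsity checks run the path
$p_\alpha \in \{25, 50, 100, 200\}$ at fixed $q_\beta = 100$. These
sizes were chosen so the whole suite completes in minutes while keeping
each check at the scale that makes it meaningful.

## Known limitations

* **Deflation residue.** Deflating by *estimated* latent variables
  induces a small genuine cross-block dependence in the residual
  matrices: the estimated latent is a function of both blocks' noise, so
  projecting it out aligns the two noise fields. Under strong signals
  with oversized supports (requested 100 against true 80/50/30), the
  first spurious component after the real ones can occasionally carry an
  out-of-sample correlation large enough to test significant, and the
  excess weight slots of a late real component can latch onto the
  residue of earlier ones, producing small dips in the adjusted-CPEV
  curve. Deflating by the true latents (available in simulations)
  removes the effect entirely, which localizes it in the deflation
  scheme rather than the implementation. Practically: treat a
  marginally significant late component with a large gap between its
  in-sample and out-of-sample correlation with suspicion.
* **Order stability.** Components of similar strength can be estimated
  in different orders by independently initialized runs; use
  `init = "decomposition"` where cross-run comparability matters (see
  above).
* **Ties.** Exactly tied magnitudes at the threshold boundary (e.g.
  duplicated features) shrink to zero and can make a component sparser
  than requested or degenerate; ties are resolved deterministically by
  index and warned about.
* The number of components is not chosen automatically; the adjusted
  explained-variance curve is reported for the user to judge.
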
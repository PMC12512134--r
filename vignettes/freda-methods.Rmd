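---
title: "Federated domain adaptation for regression: models, protocols, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated domain adaptation for regression: models, protocols, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A regression model — the motivating case is an epigenetic clock predicting
chronological age from DNA methylation — must generalize from labeled
*source* data to an unlabeled *target* domain whose feature dependencies
have drifted (different tissue, cohort, or laboratory). On top of the
covariate shift, the source data are scattered across institutions that
cannot pool raw samples. `freda` simulates, in one process, the full
privacy-preserving pipeline that solves both problems at once: source
clients, a target client, and a data-free aggregator exchange only masked
or aggregated messages, yet the target ends up with tissue-specific
adaptive models mathematically identical to what a pooled analysis would
produce.

The pipeline has four phases:

1. **Feature models.** One Gaussian-process regressor (GPR) per feature
   $f$ regresses that feature on all remaining features, trained on the
   distributed source data.
2. **Weights.** The target client scores each of its observations against
   the per-feature predictive distributions and converts group-averaged
   confidences into elastic-net penalty weights.
3. **Regularization strength.** $\lambda$ is selected per target group,
   either from domain-similarity scores or by source-side
   cross-validation.
4. **Final models.** One weighted elastic net per target group is trained
   federatively (FedAvg) on all source data and shipped to the target.

## Feature models

For feature $f$, with $X_{\neg f}$ the source matrix without column $f$
and $x_f$ that column, the linear-kernel GPR uses

$$K = \sigma_k^2 X^S_{\neg f} X^{S\top}_{\neg f} + \sigma_\varepsilon^2 I,
\qquad K_* = \sigma_k^2 X^T_{\neg f} X^{S\top}_{\neg f}, \qquad
K_{**} = \sigma_k^2 X^T_{\neg f} X^{T\top}_{\neg f},$$

giving the predictive mean $K_* K^{-1} x^S_f$ and covariance
$K_{**} - K_* K^{-1} K_*^\top$. $K_{**}$ carries no noise term: the
confidence scores ask how far an observation sits from the *latent*
predictive distribution, and we keep that (noise-free) form; adding
$\sigma_\varepsilon^2$ would only widen all intervals uniformly. Only the
diagonal of the covariance is ever released — the downstream confidence
computation uses per-sample standard deviations and nothing else.

Hyper-parameters maximize the local marginal likelihood on each client.
The implementation eigendecomposes the local Gram matrix once per feature,
making every objective evaluation $O(n)$, and runs box-constrained
L-BFGS-B in log-parameter space (bounds $[10^{-6}, 10^6]$, start $(1,1)$,
single start by default with configurable restarts). Client optima are
then averaged — unweighted, matching a plain "global average"; a
sample-size-weighted variant sits behind `weights` in
`aggregate_hyperparams()`. Per-client optima are statistics of local data,
so their average depends on how the data are partitioned; what is
partition-invariant (and what the tests pin down to $10^{-6}$) is the
masked protocol itself: given the same hyper-parameters and the same
clients, the federated predictive means and variances equal the pooled
closed form.

Numerical choices: kernel solves go through a jittered Cholesky with a
ladder starting at $10^{-8}\,\overline{\mathrm{diag}}$ and escalating
tenfold up to three times; predictive variances are clipped at zero and an
error is raised below $-10^{-6}$; degenerate (zero-variance) predictions
are floored at $\sigma = 10^{-12}$ so that an exact match still scores
confidence 1.

## Privacy mechanisms

**Randomized encoding.** All parties expand a shared seed into a mask
$M \in \mathbb{R}^{d\times P}$ with $d > P$ (default $P + 10$), full
column rank by construction (resampled up to 5 times otherwise). Each
party encodes $\tilde X_p = X_p L_p (MM^\top)^{1/2}$ with $L_p M = I$; the
aggregator multiplies encodings pairwise and the masks cancel, leaving
exactly the cross-party Gram matrices $X_p X_q^\top$ — never the data, and
not even its dimensionality, since encodings live in $d$ columns. The
left inverse is the Moore–Penrose form $(M^\top M)^{-1} M^\top$, identical
across parties; a per-party randomized null-space component is available
behind `randomize_left_inverse` (the cancellation identity needs only
$L_p M = I$). The symmetric root is computed by eigendecomposition with
negative eigenvalues clipped at zero.

**Secure aggregation.** Scalar and vector aggregates (hyper-parameter
means, FedAvg updates) travel as fixed-point residues modulo $2^{64}$
(32 fractional bits by default), masked by pairwise zero-sum streams: each
unordered pair expands a shared seed, one adds and the other subtracts, so
the masks cancel *exactly* in the ring — implemented as two 32-bit limbs
in doubles, every intermediate below $2^{53}$, hence bit-exact. The
aggregator sees only uniformly-distributed residues.

**Masked predictive mean.** The aggregator holds $A = K_* K^{-1}$ but not
the feature columns; clients hold columns but must not see $A$ (it encodes
target-side structure). The aggregator therefore ships each client a
row-masked block of $CA$ (with $C$ a random well-conditioned
$n_t \times n_t$ matrix, condition number below $10^8$, resampled up to 5
times), clients return $C A_{[:,i]} x_f^{(i)}$, and the target sums the
contributions and removes $C^{-1}$.

**Transcript and audit.** Every cross-party message is recorded with an
MD5 digest of its payload. The audit fails if any digest matches a raw
data matrix, a single feature column, a label vector, or if mask seed
material reaches the aggregator. This is an information-flow check against
the honest protocol, not a cryptographic proof; the threat model is
semi-honest throughout.

## Confidences and weights

For target sample $m$ and feature $f$ the confidence is the two-sided tail
probability $2\Phi(-|x_{m,f} - \mu_f(x_m)|/\sigma_f(x_m))$: the
probability of a value at least as extreme under the predictive normal.
(The tail form needs the negated standardized deviation inside $\Phi$;
with a positive sign the score would live in $[1,2]$ and the weight law
below would go negative.) Confidences are averaged within each target
group — tissue-specific weighting, one model per tissue — and mapped to
penalty weights $w_f = (1 - c_f)^k$ with $k = 3$ by default: features
whose source-learned dependency structure still explains the target well
are penalized lightly, discrepant ones heavily; larger $k$ sharpens the
contrast.

## Weighted elastic net and federated training

The final models minimize

$$\lVert y - X\beta\rVert^2 + \lambda\Big(\alpha \sum_f w_f |\beta_f| +
\tfrac{1-\alpha}{2}\sum_f w_f \beta_f^2\Big), \qquad \alpha = 0.8,$$

with the residual sum of squares deliberately unnormalized, so the
meaning of $\lambda$ scales with $n$ — the selection machinery works on
this fixed convention end to end. An unpenalized intercept is included
(labels are roughly centered but the synthetic generator leaves a
residual offset for the intercept to absorb).

FedAvg runs 100 global rounds of 20 full-batch local steps, with the
learning rate decaying exponentially from $10^{-4}$ to $10^{-5}$. Each
local step is a *proximal* gradient step: a gradient step on the smooth
part followed by soft-thresholding at $lr \cdot \lambda \alpha w_f$. A
plain L1 subgradient was tried first and rejected: at the top of the
default $\lambda$ grid its iterates oscillate around zero with objective
increases of order $lr(\lambda\alpha w)^2$, permanently triggering the
divergence guard; the proximal step is monotone at stable learning rates
and produces exact zeros. The guard remains: if a local slice increases
the local objective, the learning rate is halved and the slice retried (5
times) before a training error. Each client's residual term is scaled by
$n_S / n_i$, which makes the sample-size-weighted FedAvg average of local
updates match the pooled objective's geometry under any partition — with
one client, federated training *is* centralized gradient training (up to
the $2^{-32}$ resolution of the secure-aggregation codec).

The reference solver (`centralized_wen_oracle()`) is exact proximal
coordinate descent with per-coordinate closed-form soft-thresholding,
iterated to a $10^{-13}$ coordinate-change tolerance; tests verify KKT
residuals below $10^{-8}$ and cross-check against `glmnet` (on a
unit-variance response, where `glmnet`'s internal response standardization
does not rescale the ridge term; the mapping is then
$\lambda_{\texttt{glmnet}} = \lambda / (2n)$).

## Selecting the regularization strength

Cross-validation on the target is impossible without target labels, so
the default path leans on prior knowledge: the target groups are split
into *fit* groups (labels assumed available; the three alphabetically
first groups by default — three anchor points because a two-point
log-$\lambda$ line proved explosively extrapolation-prone) and held-out
groups. For each fit group, weighted elastic nets are trained across a
15-point logarithmic grid on $[10^{-3}, 10^2]$ and the $\lambda$
minimizing the group's MAE — always in chronological years, after the
inverse age transform — is selected, ties going to the smaller $\lambda$.
A least-squares line of $\log_{10}\lambda$ on the similarity score (raw
$\lambda$ spans decades, so the fit lives on the log scale — an assumption,
flagged as such) predicts $\lambda$ for the held-out groups, clipped into
the grid range. The similarity-free fallback (`lambda_mode = "cv"`)
selects $\lambda$ by source-side cross-validation with folds stratified
within clients.

## The age transform

Labels are transformed ages: logarithmic below the adult threshold
(default 20 years) and linear above it,
$\log\frac{a+1}{A+1}$ vs $\frac{a-A}{A+1}$, continuous and strictly
increasing; the exact inverse maps predictions back to years for every
MAE the package reports. Predictions below the transform's image are
clamped to its lower boundary before inversion.

## What the synthetic generator emulates — and what it does not

`shift_spec()` defaults define the study conditions used throughout the
tests: $P = 50$ features, $200$ pooled source samples, $60$ target
samples in 4 groups, a rank-5 latent factor model $X = ZW + \varepsilon$
with unit-norm loading columns and idiosyncratic noise 0.3, a linear
label model on 10 unperturbed features (coefficients $\pm 0.2$, intercept
0.5, label noise 0.15), and 10 perturbed features whose loading directions
are rotated in the target, $w \mapsto (w + s\,u)/\sqrt{1+s^2}$, with
per-group severities ramping over $[0.25, 1] \times$ `shift_strength`
(default 2). The latent-factor construction is deliberate: the GPR
feature models assume linear inter-feature dependencies, so parameter
recovery and shift detection are well-posed, and the strong collinearity
makes the non-adaptive baseline genuinely vulnerable — the elastic net
spreads coefficient mass onto perturbed features that are informative on
the source but rewired on the target. Group similarities are emitted as
$1/(1+s_g)$, a monotone stand-in for the expression-derived tissue
similarities a real deployment would supply.

What it does *not* emulate: beta-value boundedness of real methylation
data, probe-level noise structure, missing values, nonlinear
feature–feature or feature–age relationships, or tissue-specific mean
shifts. Passing tests show that the protocols compute the pooled
mathematics exactly and that the adaptation mechanics detect planted
dependency shifts; they do not certify performance on real methylation
cohorts, whose headline errors depend on data this package deliberately
does not download.

Problem sizes in the test-suite were chosen so the full suite and the
acceptance script each run comfortably on a single CPU: protocol
equivalence at $P = 50$, $n_S = 200$, $n_t = 60$; Monte-Carlo properties
over 20 seeded runs.

## Known limitations

* Linear kernels only; no sparse or inducing-point approximations, so
  feature-model training is $O(P \cdot n_S^3)$ at worst (the
  eigendecomposition trick makes the hyper-parameter search cheap, the
  kernel solves dominate).
* The audit checks message digests against the honest run's private
  payloads; it cannot detect information leaked through clever encodings,
  and is not a substitute for a formal security analysis.
* All roles run in one process; the message layer is an interface behind
  which a real transport could be swapped, but no networking, key
  exchange, or dropout handling is provided.
* Per-client hyper-parameter optimization is per feature (each feature's
  model is optimized independently); sharing hyper-parameters across
  features would be cheaper but is not what the averaging protocol
  describes.
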
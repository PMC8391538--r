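---
title: "Differentially private rejection ABC: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentially private rejection ABC: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcdp)
```

## The problem

Simulator-based models — outbreak models, ecological and population-genetic
processes — often have intractable likelihoods, and approximate Bayesian
computation (ABC) replaces likelihood evaluation with simulation: draw
$\theta_t \sim \pi(\theta)$, simulate a pseudo dataset $Y_t$, and accept
$\theta_t$ when a distance $\rho(Y_t, Y^*)$ to the observed data $Y^*$ falls
below a threshold $\epsilon_{abc}$. The accept/reject indicator is the only
step that touches $Y^*$ — but it does touch it, repeatedly, and in
applications such as disease-outbreak modelling each record of $Y^*$ is one
person's data. This package releases the indicator stream under pure
$\epsilon$-differential privacy (DP): the log-ratio of output probabilities
under any two datasets differing in one record is bounded by
$\epsilon_{total}$.

The mechanism is the sparse vector technique (SVT). Privacy cost is paid
only for released *acceptances* — arbitrarily many rejections are free — so
the total budget is a function of the acceptance cap $c$, not of the stream
length $T$. That matches ABC's economics: $c \ll T$ posterior samples from
a long prior stream.

## The algorithm

With threshold-noise scale $b$:

1. Draw a noisy threshold $\hat\epsilon_{abc} = \epsilon_{abc} + m$,
   $m \sim \mathrm{Lap}(b)$.
2. For $t = 1, \dots, T$: compute $\rho_t = \rho(Y^*, Y_t)$ (clipped at $C$
   if configured), draw $\nu_t \sim \mathrm{Lap}(2b)$, and release
   $\tilde\tau_t = \mathbf{1}[\rho_t + \nu_t \le \hat\epsilon_{abc}]$.
3. On each acceptance, optionally redraw the noisy threshold
   (`resample = TRUE`).
4. Stop after $c$ acceptances or at the end of the stream.

The budget identity ties $b$ to the total loss:
$$\epsilon_{total} = \begin{cases}
  (c+1)\,\Delta_\rho / b & \text{resample = FALSE},\\
  2c\,\Delta_\rho / b    & \text{resample = TRUE},
\end{cases}$$
where $\Delta_\rho$ is the distance's sensitivity — the maximum change of
$\rho(Y^*,\cdot)$ when one record of $Y^*$ is replaced. `noise_scale()`
solves this for $b$; `budget_of_noise_scale()` is its exact inverse, and the
two are tested as a round-trip. `epsilon_total = Inf` is an explicit
sentinel mapping to $b = 0$: the non-private reduction is then *exact*
(`draw_laplace(n, 0)` returns hard zeros), which makes the reduction
testable rather than approximate.

Acceptance uses the non-strict inequality $\hat\rho_t \le \hat\epsilon_{abc}$;
with noise, ties have measure zero, so the convention is inert but fixed.
The noise draw order is part of the contract (threshold first, one distance
draw per step, threshold redrawn immediately on acceptance when resampling),
so seeded runs are bit-reproducible.

If the stream ends with fewer than $c$ acceptances the run is still valid:
the claimed $\epsilon_{total}$ remains an upper bound on the loss, because
the composition argument counts at most $c$ above-threshold releases. The
accounting therefore reports the claimed budget, never a "recomputed" one,
and the trace flags the shortfall.

## The distance: MMD

The default $\rho$ is the maximum mean discrepancy with a Gaussian kernel
$k(x,y) = \exp(-\lVert x-y\rVert^2/(2l^2))$, estimated by the biased
V-statistic (diagonal terms included),
$$\widehat{\mathrm{MMD}}^2 = \frac{1}{m^2}\sum_{i,j}k(x_i,x_j)
 + \frac{1}{n^2}\sum_{i,j}k(y_i,y_j)
 - \frac{2}{mn}\sum_{i,j}k(x_i,y_j),$$
and $\rho = \sqrt{\widehat{\mathrm{MMD}}^2}$. Two deliberate choices:

* **V-statistic, not U-statistic.** The V-statistic is the squared RKHS
  norm of the difference of empirical mean embeddings, hence nonnegative,
  so its square root is well defined. Values in $(-10^{-12}, 0)$ arising
  from floating-point cancellation are truncated to zero before the root.
* **Root-MMD, not squared MMD.** The sensitivity bound
  $\Delta_\rho = 2\sqrt{B_k}/N$ and the sup bound $2\sqrt{B_k}$ hold on the
  root scale, so privacy calibration is only coherent there. We also
  threshold $\epsilon_{abc}$ on the root scale; thresholds quoted for
  kernel-ABC experiments are ambiguous between the two scales, and this
  package fixes root-MMD by convention.

For the Gaussian kernel $B_k = 1$ for every bandwidth, so
$\Delta_\rho = 2/N$: the privacy noise shrinks as $1/N$ at fixed budget,
which is the entire reason private ABC is usable for moderate $N$ and
hopeless for tiny $N$ (see the flip probability below). The estimator
accepts $m \neq n$, but the sensitivity is always computed from the size
$N$ of the *private* dataset.

The bandwidth defaults to the median heuristic — the median pairwise
Euclidean distance — computed on pseudo-data only, so it costs no privacy.
The pair enumeration is $O(n^2)$ and is capped at 1000 pooled points via a
seeded subsample; the cap only stabilizes the heuristic's estimate, whose
sampling variability is far below the scale that would matter for
acceptance decisions.

A weighted-L2 distance on summary vectors is provided for models compared
through fixed summaries. It has no intrinsic sensitivity bound; the
supported pattern is a clipping bound $C$ (`clip_distance()`, applied
before noise) plus an **explicit** user-supplied `sensitivity`. The package
refuses `sensitivity = "auto"` there: after clipping, the worst-case
single-record change depends on the summaries' structure, and guessing
(e.g. assuming $\Delta_\rho = C$) could silently understate the privacy
loss if wrong in either direction. This is a correctness-over-convenience
decision.

## Noise theory: what the indicators cost in accuracy

The accept/reject comparison depends on the noise only through
$Z = m - \nu \sim \mathrm{Lap}(b) - \mathrm{Lap}(2b)$, with density
$$f_Z(z) = \frac{1}{6b}\left[2e^{-|z|/(2b)} - e^{-|z|/b}\right],
\qquad
G_b(a) = \int_a^\infty f_Z = \frac{1}{6}\left[4e^{-a/(2b)} - e^{-a/b}\right].$$
The probability that a private indicator differs from the non-private one
at a step with raw distance $\rho_t$ is exactly
$G_b(|\rho_t - \epsilon_{abc}|)$: one half at the threshold, decaying
exponentially in the gap. `flip_prob_table()` tabulates this over a grid of
$(N, c, \epsilon_{total})$ — the design table for choosing $c$: with
$N \sim 10$ records even large budgets leave appreciable flip rates, while
at $N \sim 10^3$ the flip probability collapses to zero at modest budgets.

Two closed-form accuracy bounds compare the private and non-private
posterior expectations of any $f(\theta)$ over the same $T$ steps, with
$K_T = \max_t \lVert f(\theta_t)\rVert_2$ and $c'$ the non-private
acceptance count:

* expected L2 gap $\le \frac{2K_T}{c'}\sum_t G_b(|\rho_t - \epsilon_{abc}|)$
  (`expected_error_bound()`);
* $P[\text{gap} \le a] \ge 1 - \frac{4K_T}{3ac'}
  \sum_t e^{-|\rho_t-\epsilon_{abc}|/(2b)}$ (`error_tail_bound()`), which
  can be negative — vacuous — and is returned as-is with a `vacuous` flag
  rather than clipped, so users can see *how* uninformative it is.

Since $b = O(1/N)$, both bounds vanish as $N \to \infty$. Conventions:
Heaviside $H(0) = 1$ in the CDF (both conventions give $F_Z(0) = 1/2$;
fixed for determinism); at $b = 0$ the flip probability is defined as 0 and
$f_Z, G_b, F_Z$ are not evaluated. Test oracles check the closed forms
against adaptive quadrature (absolute tolerance $10^{-10}$) and against
Monte-Carlo samples of $\mathrm{Lap}(b) - \mathrm{Lap}(2b)$; the closed
forms are the production path.

## Simulators and what the tests do (and do not) show

Two self-contained generative models ship with the package.

**Uniform mixture (parameter-recovery testbed).** A flat Dirichlet prior
on the 5-simplex and likelihood
$P(y\mid\theta) = \sum_{i=1}^5 \theta_i\,\mathrm{Unif}[i-1, i)$, with
ground truth $\theta^* = (0.25, 0.04, 0.33, 0.04, 0.34)$. Sampling is
two-stage (multinomial component, then uniform position) so bin occupancy
is exactly multinomial and testable. The reference configuration uses
$N = n = 5000$ points and $T = 5000$ prior draws; the shipped test suite
runs a scaled configuration, $N = n = 1000$, $T = 2000$,
$\epsilon_{abc} = 0.05$, $c = 10$, four independent streams with five noise
replicates each — sizes chosen so the whole suite runs in minutes on one
CPU while leaving the qualitative conclusions
(recovery of $\theta^*$ by non-private ABC; mean squared error
non-increasing in $\epsilon_{total}$ over $\{0.5, 1, 10, \infty\}$)
unchanged.

**Cubic outbreak counts.** Daily case counts over 18 days modelled by
$y(t) = a_3 + a_2 t + a_1 t^2 + a_0 t^3$ (coefficient vector supplied as
$(a_0, a_1, a_2, a_3)$: cubic term first, intercept last) with independent
$\mathcal{N}(0,1)$ priors on all four coefficients. Real early-epidemic
count series of this shape are typically downloaded from surveillance
authorities; `synthetic_outbreak_counts()` is a synthetic stand-in —
18 daily counts from a noisy cubic trend, default coefficients
$(0.06, -0.4, 5, 0)$ and count noise SD 10, chosen once to emulate a rise
from single digits to roughly 300 cases/day — so everything runs offline.
Because no canonical distance exists for this model, the pseudo-data are
the length-18 count vectors themselves and the distance is (clipped)
weighted L2 on them; this is an interpretation fixed by convention, as is
the day-unit time grid $t = 1..18$.

What passing tests show: the mechanism, calibration and closed-form theory
are internally consistent and match independent oracles on data whose
generating process is fully known. What they do not show: robustness to
real data's features absent from these simulators — temporal dependence,
overdispersion, reporting artifacts, model misspecification. The privacy
guarantee is unconditional (it never depends on the data distribution);
the *accuracy* statements are what the simulators probe.

**TB-style birth–death models** are out of scope: their simulator and
summary statistics are defined externally. The supported integration point
is exactly the clipped weighted-L2 distance with explicit sensitivity, via
`generate_pair_stream()` over a user-supplied simulator.

## Reproducibility and numerical choices

* Streams are lazy and per-pair seeded: pair $t$ derives its own seed from
  the master seed, so early-stopped runs skip unneeded simulation while
  out-of-order access stays bit-identical. Stream access never perturbs
  the caller's RNG stream.
* Replicate seeds derive from a master seed by a fixed counter scheme
  (`master * 1009 + counter`, reduced mod $2^{31}-1$).
* `run_experiment()` computes each raw distance once (in the baseline
  pass) and replays Laplace noise over the recorded distances for the
  private modes; the mechanism depends on the data only through the
  distances, so this is the same algorithm, just without recomputing
  kernel sums. `run_abcdp()` keeps the lazy early-stopping path for
  standalone use.
* Kernel double sums run in compiled code (`src/mmd.cpp`); an R double
  loop serves as the independent oracle in the tests.
* Serialized results contain only the DP release — indicators, accepted
  parameters, accounting. Raw and noisy distances stay in the in-memory
  trace, flagged as diagnostics; by post-processing invariance the release
  derived from the indicators needs no further budget.

## Known limitations

Pure DP with linear composition only (no approximate DP, no advanced
composition); rejection ABC only (no sequential Monte Carlo, whose
per-proposal weights would charge budget at every step); Gaussian kernel
only; the MMD cost is $O(N^2)$ per stream step, which is the practical
ceiling on $N$; and for very small $N$ (tens of records) the flip
probability stays high at any usable budget — the honest reading is that
such datasets cannot support many private posterior samples, not that a
better mechanism is hiding here.
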
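---
title: "Bayesian multi-dipole localization by adaptive Sequential Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian multi-dipole localization by adaptive Sequential Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipoleSMC)
```

## The model

MEG/EEG sensor data in a short analysis window are modeled as the
superposition of a small, unknown number of equivalent current dipoles plus
Gaussian noise:

$$ y(t) \;=\; \sum_{i=1}^{N} G(r_i)\, q_i(t) \;+\; \varepsilon(t),
\qquad \varepsilon(t) \sim \mathcal N(0, \sigma_\varepsilon^2 I). $$

Here $G(r_i)$ is the lead-field block of a point source at location $r_i$
(3 columns per vertex in free-orientation mode, 1 signed column when
orientations are fixed), $q_i(t)$ its moment, and $\sigma_\varepsilon$
absorbs both measurement noise and forward-modeling error. Within the
window the number and locations of the active sources are assumed fixed;
only the intensities vary, with an independent Gaussian moment draw
$q \sim \mathcal N(0, \sigma_q^2 I)$ per analyzed sample.

The unknowns are a priori independent,
$p(N, R, Q) = p(N)\,p(R)\,p(Q)$. Because the model is conditionally linear
Gaussian in $Q$, the posterior factorizes as
$p(N,R,Q \mid y) = p(Q \mid N,R,y)\, p(N,R \mid y)$: the first factor is an
analytic Gaussian (computed by `conditional_moment_posterior()`), and the
dipole moments can be integrated out of the likelihood in closed form
(`log_marginal_likelihood()`), so the sampler only ever explores the
discrete configuration space $(N, R)$ and, optionally, the scalar
$\sigma_q$. Each analyzed sample contributes
$\log \mathcal N(y_t;\, 0,\; \sigma_q^2 G_R G_R^\top +
\sigma_\varepsilon^2 I)$.

### Priors

* **Number of dipoles.** $N$ is known a priori only to be small. The
  default $p(N)$ is a Poisson pmf with mean 0.25 truncated to
  $\{0,\dots,n_{\max}\}$ ($n_{\max} = 10$): a mild sparsity prior that
  still lets the likelihood dominate at realistic SNR. Both the pmf and
  $n_{\max}$ are user-replaceable in `source_prior()`.
* **Locations.** A configuration is an unordered set of distinct vertices.
  With per-vertex weights $w_v$ (uniform by default; non-uniform weights
  implement high/low-probability search regions, and zero-weight vertices
  are excluded outright), a set $S$ with $|S| = N$ has prior probability
  $\prod_{v \in S} w_v / e_N(w)$, where $e_N$ is the $N$-th elementary
  symmetric polynomial — the exact normalizer over distinct sets, computed
  once by dynamic programming. Counts exceeding the number of
  positive-weight vertices are impossible ($e_N = 0$) and their prior mass
  is removed. Initialization samples this prior exactly: iid draws from
  $w$, rejected until distinct.
* **Moment scale.** $\sigma_q$ can be fixed, or given a log-uniform
  hyper-prior on $[\sigma_q^{\min}, 10^3 \sigma_q^{\min}]$ so that the
  reconstruction is insensitive to the unknown order of magnitude of the
  source strengths. When resolved automatically,
  `estimate_dip_mom_std()` returns
  $\hat\sigma_q = 15 \max_t |y| / \max_v \lVert G_v \rVert_F$ — a dipole of
  that strength at the most sensitive vertex comfortably explains the data
  peak; the estimate is degree-1 homogeneous in the data and degree-(−1) in
  the lead field, hence scale-free. In hyper mode
  $\sigma_q^{\min} = \hat\sigma_q / \sqrt{1000}$, centering the estimate on
  the log-scale support.
* **Noise level.** By default
  $\sigma_\varepsilon = 0.2 \max |y|$ over the analysis window — a
  rule-of-thumb for the combined measurement and forward-model error. It is
  the main tuning knob: smaller values make the sampler chase the data with
  more dipoles; larger values favor sparse, approximate fits. A
  baseline-interval estimate (`--noise-std baseline:T0:T1`, pooled standard
  deviation over a pre-stimulus window) and explicit values are also
  available.

## The sampler

`run_sesame()` is a Sequential Monte Carlo sampler over the bridging
distributions $\pi_\gamma \propto p(y \mid N,R,\sigma_q)^\gamma\, p(N)
p(R) p(\sigma_q)$, from the prior ($\gamma = 0$) to the posterior
($\gamma = 1$). Each iteration applies, per particle, one
Metropolis-Hastings move chosen uniformly among:

* **birth** — propose a new dipole at a vertex drawn from $w$; rejected
  automatically beyond $n_{\max}$ or onto an occupied or zero-weight
  vertex; the acceptance ratio carries the birth/death proposal densities;
* **death** — remove a uniformly chosen dipole (reverse of birth);
* **update** — random-walk one dipole over a precomputed spatial kernel
  (transition weight $\propto e^{-d^2/2s^2}$ over vertices within $3s$,
  self excluded; $s$ is the source space's `kernel_scale_m`, enlarged
  automatically until the neighbor graph is connected so the move is
  ergodic), with the forward/reverse kernel ratio in the acceptance
  probability; in hyper mode the same move perturbs $\log \sigma_q$ by a
  Gaussian step whose Jacobian cancels the log-uniform prior inside its
  support.

The move kernel is implemented once in C++ (RcppArmadillo) and drives both
the exported single-particle `mcmc_move()` and the full sweep; it draws all
randomness from R's RNG, so runs are bitwise reproducible given
`settings$seed`.

After each sweep the tempering increment is chosen adaptively: bisection
(to $10^{-6}$ on $\gamma$) so that the reweighted effective sample size is
0.99 of the current one, capped at $\gamma = 1$. Weights follow the
importance rule $w_i \propto w_i\, \ell_i^{\Delta\gamma}$; when the ESS
falls below $I/2$ the population is resampled systematically (the
lowest-variance standard scheme; with equal weights every particle survives
exactly once). The run stops at $\gamma = 1$, optionally followed by
post-burn sweeps that decorrelate the final population; exceeding
`max_iterations` (default 1000; a fast 50-iteration preset suits
interactive use) raises a convergence error carrying the partial state. The
per-iteration log (gamma, ESS, acceptance rate per move type) is returned
so mixing can be audited.

## Output

`summarize_posterior()` assembles: $p(N \mid y)$; the modal count
$\hat N$ (ties break toward fewer dipoles — parsimony); the per-vertex
location probability map conditional on $\hat N$ (each particle contributes
its weight split equally over its dipoles); $\hat N$ greedy map peaks with
an exclusion radius (default 2 cm), each reported with its credibility mass
(the suppressed neighborhood's probability, giving every reported dipole
its own uncertainty number); the posterior-mean source time courses at the
peaks (with moment amplitudes in free-orientation mode); goodness of fit
$\mathrm{GOF} = 1 - \lVert y - \hat y\rVert_F^2 / \lVert y \rVert_F^2$;
the spatial dispersion
$\mathrm{SD} = (\sum_v m_v\, d(v, \text{nearest dipole})^2)^{1/2}$ of the
map (meters; 0 iff the map is concentrated on the dipoles); and
*alternative solutions* — a full map-and-peaks entry for every count whose
posterior mass reaches `alt_threshold` (default 0.1), so a 60/40 split
between a one- and a two-dipole explanation is surfaced rather than
hidden. For simulation studies with known truth the package also provides
the OSPA set distance (exact min-cost assignment, cutoff 3 cm) and the map
localization discrepancy (mean distance from each true dipole to the
nearest map peak).

## The synthetic-data generator

`simulate_experiment()` builds the whole study fixture: a Fibonacci-lattice
hemispherical magnetometer array (radius 0.12 m, radial orientations); a
source space of 200 quasi-uniform points in an 0.08 m ball (free
orientation) or a spherical shell with outward fixed orientations (a
cortical stand-in); the free-space magnetic-dipole lead field
$B(r) = \tfrac{\mu_0}{4\pi}\, q \times (r - r_0) / \lVert r - r_0
\rVert^3$ projected on the sensor orientations; sinusoidal source time
courses of peak amplitude $10^{-8}$ A·m (a typical equivalent-dipole
strength) over 10 samples; and iid Gaussian sensor noise scaled to a target
SNR $\lVert G Q \rVert_F / (\sigma_\varepsilon \sqrt{mn})$, default 10.

Two physics notes. The free-space dipole law is deliberately simple — linear
in the moment and checkable pointwise — but it is not a volume-conductor
head model; absolute field values are not physiological. And, as in real
MEG, the radial moment component at a vertex is silent for radially
oriented sensors ($\;(q \times (r - r_0)) \cdot r$ vanishes for radial
$q$), so each free-orientation gain block has rank 2; the generator
therefore draws tangential true moments (the observable subspace), and the
moment posterior is solved through an SVD ridge factorization that remains
exact for rank-deficient gains, including the noiseless limit where it
converges to the minimum-norm least-squares solution. What passing tests on
these fixtures demonstrate is the correctness of the *inverse* machinery —
which only ever sees a lead-field matrix; they say nothing about forward-
model fidelity on real heads, where users supply their own lead field.

`enumerate_posterior()` is the package's exact reference: for problems
small enough to enumerate (at most 2 dipoles, guarded at $10^4$
configurations) it computes every configuration's marginal likelihood times
its prior and normalizes by log-sum-exp, integrating the hyper-prior over
$\sigma_q$ with a 200-point log-spaced trapezoid rule. The accuracy suite
checks the SMC estimates of $p(N \mid y)$ and of the conditional maps
against it within three Monte Carlo standard errors on twenty seeded
problems, and reproduces qualitative behavior expected of the model — the
posterior mean of $N$ is non-increasing as $\sigma_\varepsilon$ rises
through 6.5%, 20% and 65% of the data peak.

## Numerical choices and problem sizes

* Vertex ids are 1-based, following R convention; coordinates are meters,
  moments A·m.
* Configurations store their vertices sorted, so permuted configurations
  are identical objects and the marginal likelihood is exactly permutation
  invariant.
* The marginal likelihood is evaluated through a Cholesky factorization of
  the $m \times m$ sensor covariance; $\sigma_\varepsilon^2 I$ keeps it
  positive definite.
* The adaptive-increment bisection tolerance is $10^{-6}$ on $\gamma$; ESS
  arithmetic is done on log-weights shifted by their maximum.
* Degenerate inputs fail loudly: all-zero analysis windows (no noise or
  moment scale can be estimated), zero lead-field blocks, sensors
  coinciding with vertices, empty analysis windows, conditioning on a
  dipole count with no posterior mass.
* Study sizes used by the tests and the acceptance script: twenty
  enumerable problems (8–12 vertices, 4–8 sensors, $n_{\max} = 2$) at
  $I = 2000$ with 20 post-burn sweeps; twenty two-dipole and twenty null
  recovery runs on the 200-vertex volume at $I = 100$; cost-scaling at
  $I \in \{100, 200, 400, 800\}$ on a 150-vertex problem. These sizes give
  stable Monte Carlo comparisons at desk scale.

## File formats

Matrices travel as TSV (`#` comments, full `%.17g` precision). Results and
source spaces are self-describing JSON written at 17 significant digits, so
every number survives a save/load round trip bitwise; each result file
embeds the resolved hyper-parameters and the seed, making any run
re-executable from its output alone, plus the full particle population,
the tempering schedule, the ESS log and the estimates. Files declare a
format version and future versions are refused explicitly.

## Limitations

* No volume-conduction forward modeling (BEM/FEM): users supply the lead
  field for real-data work.
* Gaussian noise and temporally independent moment draws; no temporal
  smoothness prior on time courses and no frequency-domain variant.
* One shared $\sigma_q$ per configuration rather than one per dipole.
* Sampling is single-threaded; cost is linear in the particle count and
  grows with the complexity of the posterior (more active sources mean
  longer tempering paths).
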
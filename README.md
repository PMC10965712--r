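# dipoleSMC

Bayesian multi-dipole source localization for MEG/EEG by adaptive
Sequential Monte Carlo.

Evoked MEG/EEG activity in a short time window is often well described by a
handful of equivalent current dipoles,

```
y(t) = Σ_{i=1..N} G(r_i) q_i(t) + ε(t),      ε(t) ~ N(0, σ_ε² I),
```

but *how many* dipoles, and *where*, is the hard part: the data depend
non-linearly on N and on the locations R = {r_i}, and a single best-fitting
configuration says nothing about its uncertainty. `dipoleSMC` is for
electrophysiologists and methods researchers who want the full
trans-dimensional posterior rather than a point estimate: the probability
of each dipole count p(N | y), per-vertex location probability maps
p(R | y, N̂), peak dipoles with credibility masses, posterior source time
courses, and alternative solutions whenever competing explanations carry
non-negligible mass.

The engine samples p(N, R | y) with a Sequential Monte Carlo sampler:
a population of weighted candidate configurations ("particles") is drawn
from the prior and annealed toward the posterior through
π_γ ∝ p(y | N, R, σ_q)^γ p(N, R, σ_q), with trans-dimensional
Metropolis-Hastings moves (dipole birth, death, and spatial random-walk
updates), adaptive tempering increments chosen by an effective-sample-size
decay rule, and systematic resampling. The dipole moments Q never enter the
sampled space: the model is conditionally linear Gaussian, so Q is
marginalized analytically — each sample contributes
log N(y_t; 0, σ_q² G_R G_Rᵀ + σ_ε² I) — and recovered afterwards in closed
form. The moment scale σ_q can carry a log-uniform hyper-prior spanning
three orders of magnitude, removing the need to guess source strength; the
noise level defaults to 20% of the signal peak. The move kernel is C++
(RcppArmadillo); runs are deterministic given a seed.

The package also ships the full synthetic-study apparatus used for its own
validation — hemispherical sensor arrays, volumetric and shell source
spaces, free-space dipolar lead fields, SNR-controlled simulated datasets,
and an exact brute-force posterior (`enumerate_posterior()`) for small
problems — plus the standard evaluation metrics GOF, OSPA, spatial
dispersion (SD) and map localization discrepancy (MLD).

## Worked example

Simulate two well-separated dipoles at SNR 10 on a 200-vertex volumetric
source space, then localize them:

```r
library(dipoleSMC)

sim <- simulate_experiment(n_vertices = 200, n_sensors = 30,
                           n_dipoles = 2, snr = 10, seed = 42)
sim$truth$config$vertices
#> [1] 40 44

fit  <- run_sesame(sim$model, sesame_settings(n_particles = 100, seed = 1))
summ <- summarize_posterior(fit)
summ
#> Posterior over number of dipoles:
#>   p(N = 2 | y) = 1.0000
#> Estimated N = 2
#> Estimated dipoles (vertex, map value, credibility mass):
#>  vertex map_value mass
#>      40   0.50000  0.5
#>      44   0.47739  0.5
#> GOF = 0.9907, spatial dispersion = 0.0006 m
```

The sampler puts all posterior mass on a two-dipole model and its map peaks
sit exactly on the simulated vertices: each peak's credibility mass of 0.5
says half of the conditional location mass lies within 2 cm of it, the GOF
of 0.9907 says the reconstruction explains 99% of the squared sensor
signal, and the small spatial dispersion (0.6 mm) indicates a tightly
focused map. Against the known truth,

```r
ospa(sim$space$positions[summ$estimated_dipoles$vertex, ],
     sim$space$positions[sim$truth$config$vertices, ])
#> [1] 6.585445e-10
```

an OSPA distance at numerical zero: both dipoles are recovered with no
localization or cardinality error. `fit$log` holds the per-iteration
tempering schedule, ESS and acceptance rates for mixing diagnostics, and
`summ$alternatives` lists every dipole count whose posterior mass reaches
0.1 with its own map and peaks.

The same pipeline is available from a shell:

```sh
inst/cli/dipolesmc simulate --output bundle --n-dipoles 2 --seed 42
inst/cli/dipolesmc run --leadfield bundle/leadfield.tsv --data bundle/data.tsv \
    --source-space bundle/source_space.json --n-particles 100 --seed 1 \
    --output bundle/result.json
inst/cli/dipolesmc inspect --input bundle/result.json
```

with `--noise-std auto|baseline:T0:T1|VALUE` and
`--dip-mom-std auto|hyper|VALUE` controlling the hyper-parameters, and an
`oracle` subcommand running the exact enumeration on small inputs.

## Vignette

`vignettes/multi-dipole-smc.Rmd` documents the model and priors, the
sampler construction (tempering schedule, move kernels, resampling), what
the synthetic generator does and does not emulate, numerical choices, and
known limitations.
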
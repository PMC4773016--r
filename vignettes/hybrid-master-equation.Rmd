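---
title: "Hybrid simulation of reaction sub-networks: model, closed forms, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid simulation of reaction sub-networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridCME)
```

## The idea

For a well-mixed mass-action reaction network, the chemical master
equation (CME) gives the exact law of the copy-number distribution, and
the Gillespie stochastic simulation algorithm (SSA) samples it exactly.
Both struggle in opposite ways: the CME's state space explodes with the
number of species, while the SSA's event count scales with total
propensity, which is dominated by abundant species.

`hybridCME` implements a partitioned simulator. The reactions are split
into a simulated group **G1** (which may change any species) and an
analytic group **G2** (which only changes its own species, here a linear
birth–death cascade). Between G1 events, the G2 sub-network's CME is
solved *in closed form*; its solution supplies

1. the **survival function** $Q(\tau)$ — the probability that no G1
   reaction fires within $\tau$ — obtained by summing an unnormalized
   ("loss-carrying") variant of the G2 master equation whose sink term
   contains *all* propensities, and
2. the **marginalized reaction probabilities**
   $p_\mu = \sum_n P(n,\tau)\, a_\mu(n)/a(n)$ used to pick the next G1
   reaction.

An event loop then mirrors the direct method: draw $\xi_1$, solve
$Q(\tau) = \xi_1$, draw $\xi_2$, pick the reaction by cumulative
probability, update the simulated species, and carry the advanced
analytic distribution forward. The abundant species (proteins) live in
G2, so each realization costs only as many events as the *rare* part of
the network fires — orders of magnitude fewer than the full SSA.

## The Poisson ansatz

Both built-in models place a linear cascade in G2. Linear birth–death
systems map Poisson (or product-Poisson) initial laws onto Poisson laws
with evolving means, so the whole G2 distribution is carried by a mean
vector $\lambda(t)$:

* **Switch** (one pool): $\dot\lambda = Km - q\lambda$, solved by
  `lambda_switch()`. The unnormalized twin replaces $q$ by the effective
  decay $\tilde q = \alpha_1 S_0 + \alpha_2 S_1 + q$ (decay plus the
  binding channels that consume a protein) giving $h(t)$, and the
  normalization integrates $\dot g = \tilde K - q h$ with
  $g(0) = \lambda(0)$ (`h_g_switch()`), where $\tilde K$ is the sum of
  the remaining propensities at the current promoter/mRNA state. Then
  $\ln Q(\tau) = h(\tau) - g(\tau)$, exactly zero at $\tau = 0$.
* **Oscillator** (a $d$-stage conversion cascade): the means obey
  $\dot\lambda_1 = Km - a\lambda_1$,
  $\dot\lambda_i = a(\lambda_{i-1} - \lambda_i)$,
  $\dot\lambda_d = a\lambda_{d-1} - q\lambda_d$, with closed-form
  exponential-polynomial solutions for the pre-terminal stages and an
  incomplete-gamma sum for the terminal one (`lambda_griffith()`). The
  twin cascade replaces the terminal decay by
  $\tilde q = q + \sum_i \alpha_i S_{i-1}$. We evaluate the
  incomplete-gamma factor through the regularized function
  $\gamma(j{+}1, s)/(j!\,s^{j+1})$, switching to its entire-function
  series for $|s| < 1/2$; this is numerically stable through the
  confluent point $a = \tilde q$, so no small-offset trick is needed
  when rates collide.

Two analytic subtleties deserve a note, because they are easy to get
wrong and the package's oracle settles both. First, summing the
unnormalized solution over $n$ gives $e^{h - g}$, with $h$ — not
$\lambda$ — in the exponent; the two differ by several percent at the
default rates. Second, the oscillator's effective terminal decay must
retain the $+q$ term: the decay channel sits in G2, so its gain *and*
loss both appear in the unnormalized equation, and only their imbalance
against the G1 sink survives in $\tilde q$. Both statements are enforced
by tests against the lattice oracle (below).

## Waiting-time sampling and its fast path

$\ln Q$ is continuous and strictly decreasing whenever the expected G1
propensity is positive, so $Q(\tau) = \xi_1$ has a unique root, found by
doubling a bracket from the first-order guess and polishing with an
Illinois regula-falsi to $10^{-12}$ relative. Because root-finding per
event would dominate the run time, the loop first tries the expansion
$\ln Q(\tau) \approx -b_1\tau + b_2\tau^2/2$ with

* $b_1 = \tilde K - Km + (\tilde q - q)\lambda(0)$ — identically the
  summed G1 propensity with the analytic species replaced by its mean
  (a tested invariant), and
* $b_2 = (\tilde q - q)(\tilde q\,\lambda(0) - Km)$ for the switch
  (resp. $(\tilde q - q)(\tilde q \lambda_d(0) - a\lambda_{d-1}(0))$),
  the exact second derivative of $\ln Q$ at zero.

The first-order root $\tau_0 = \ln(1/\xi_1)/b_1$ is accepted when the
second-order correction ratio is below `eps` (default $10^{-3}$,
configurable). We apply the bound to $|\tau_1|/(\tau_0 + \tau_1)$ —
i.e. accept when $|\tau_1/\tau_0| < \varepsilon/(1+\varepsilon)$ — so
that `eps` bounds the fast path's actual relative error, not only its
first-order estimate. In the default switch run upward of 95% of events
take the fast path; the counters returned by `simulate_hybrid()` report
the exact split per realization.

## Reaction probabilities and inverse moments

At a one-hot promoter state every G1 propensity is linear in the single
analytic species that G1 sees ($n$, or the mature conformation $n_d$):
$a_\mu(n) = c_\mu + d_\mu n$. With $n \sim \text{Poisson}(\lambda)$ and
$a(n) = D\,(n + A)$, $A = C/D$,

$$p_\mu = \frac{d_\mu}{D} + \frac{c_\mu - d_\mu A}{D}
  \left\langle \frac{1}{n + A} \right\rangle,$$

which reproduces the per-state closed forms with shifts such as
$a_1 = (r_0 + km)/\alpha_1$ for the empty switch promoter. The package
derives $c_\mu, d_\mu$ from the reaction set itself rather than
hard-coding per-state formulas, so the probabilities agree with
brute-force marginalization by construction — a property test checks
$10^{-8}$ agreement on randomized states, and `reaction_probs_griffith()`
additionally exposes an `as_printed` variant coefficient set for
comparison.

The inverse moment $\langle 1/(n+a)\rangle$ is computed two ways:

* `poisson_inverse_moment()` — an adaptive series
  $e^{-\lambda}\sum_n \lambda^n/((n+a)\,n!)$ with term-ratio stopping at
  $10^{-15}$, switching to a windowed summation around the mode for
  $\lambda > 600$ so that no intermediate under/overflows occur. This
  equals the incomplete-gamma identity
  $(-b)^{-a}[\Gamma(a) - \Gamma(a,-b)]$ analytically while avoiding a
  negative-argument incomplete gamma.
* `approx_inverse_moment()` — the three-term central-moment expansion
  $1/s + \lambda/s^3 - \lambda/s^4$, $s = a + \lambda$, exact through
  the Poisson's third central moment. Its leading neglected term is
  $\mu_4/s^5$, so the relative error is $\approx 3\lambda^2/s^4$: small
  only when $a$ dominates. The production loop uses the expansion with
  an automatic exact fallback when $a < 1$ or $\lambda < 1$; in the
  regimes the built-in models visit at event times, $a$ is of order
  $10^3$–$10^4$ and the expansion error is $\lesssim 10^{-7}$.

## What the default mode approximates

Three approximations separate the production hybrid from an exact
sampler of the partitioned process, and all are deliberate:

1. Binding and unbinding move one protein between the pool and the
   promoter; the default mode leaves the Poisson mean untouched (the
   shift operators `shift_distribution_up()`/`_down()` implement the
   exact modification, with pile-up at zero for decrements, and the
   exact-mode stepper `hybrid_step_exact()` propagates a full truncated
   vector for validation). With binding rates of $10^{-3}$–$10^{-2}$
   per protein per minute this perturbation is negligible except in the
   oscillator's low-copy troughs, where it shows up as a slight excess
   in dispersion deviations (see Validation).
2. The next-reaction identity uses the *normalized* distribution
   $P(n,\tau)$ rather than the survival-conditioned one, and that same
   $P(n,\tau)$ is carried forward — the algorithm's own convention.
3. The fast-$\tau$ path truncates $\ln Q$ at second order, guarded by
   the `eps` ratio test with exact root-finding fallback.

## The lattice oracle

Every closed form above is verified against `integrate_P()` /
`integrate_Q()`: a truncated-state-space integration of the G2 (resp.
loss-carrying) master equation at fixed simulated state, built as a
sparse generator over the product lattice and integrated with deSolve
(`lsoda`, rtol $10^{-11}$, atol $10^{-13}$). The lattice bound defaults
to $\mathrm{mean} + 10\sqrt{\mathrm{mean}} + 20$ per species; transitions
that would leave the lattice are suppressed entirely, so truncation
error accumulates as visible boundary mass, and any boundary mass above
$10^{-12}$ triggers enlargement and a restart. The joint oscillator
lattice grows geometrically with $d$, so oracle runs are restricted to
small $d$ (the tests use $d = 2$); the production $d = 10$ model is
verified component-wise (cascade means against direct ODE integration)
and end-to-end against the full SSA.

## Validation strategy and what it shows

The acceptance-style tests (and `scripts/acceptance.R`) recompute:

* Poisson preservation: lattice solution vs `Poisson(lambda(t))`, total
  variation below $10^{-8}$ at $t \in \{1, 10, 100\}$ min.
* Survival equivalence: closed form vs lattice sum ($10^{-6}$, achieved
  at $\sim 10^{-11}$) on randomized states, and vs the empirical
  first-G1-event curve of $10^4$ full-SSA runs within a 99%
  Dvoretzky–Kiefer–Wolfowitz band.
* Probability marginalization: closed forms vs brute-force lattice
  summation at $10^{-8}$ on 100 randomized states per model.
* Ensemble agreement with the exact SSA, at a reduced but meaningful
  scale chosen to keep the default suite in minutes: 1000 realizations
  per arm to $t = 500$ min for the switch (grid step 10 min), 300
  realizations to $t = 700$ min for the $d = 10$ oscillator. Means and
  standard deviations are compared per grid point by $z$-scores with
  quadrature-combined, fourth-moment-based standard errors. With a few
  hundred correlated comparisons, a hard "every $|z| \le 3$" rule is
  miscalibrated — independent exact-vs-exact control ensembles exceed it
  regularly — so the band is the self-consistency calibration: more than
  99% of $z$-scores within $\pm 3$, plus $\chi^2$ agreement ($p > 0.01$)
  of unit-bin mRNA histograms at $t = 150$ and $300$ min, and matching
  oscillation phase and amplitude of the ensemble-mean mRNA.
* Hidden-species recovery: although the hybrid never simulates the
  protein, its ensemble mean follows the linear system
  $\dot{\bar n} = K\bar m - q\bar n$ (or the conversion chain) driven by
  the hybrid's $\bar m(t)$; the reconstruction must sit within the
  combined 3-SE band of the SSA's directly simulated protein mean.

Passing these shows the hybrid reproduces the exact process *under the
models' published rate sets and initial conditions* (empty promoter, no
transcripts or proteins). The synthetic regime it does not probe:
non-mass-action kinetics, partitions whose analytic half is nonlinear
(no Poisson ansatz), and parameter corners where binding rates are large
enough that the ignored single-protein shifts matter. The residual
signature of that last approximation is already visible as a small
excess of dispersion deviations in the oscillator's troughs.

## Numerical and design choices

* **Rates** are per minute; the built-in parameter sets are the models'
  published values (`switch_params()`, `griffith_params()`).
* **Promoter states** are one-hot indicator species, so binding and
  unbinding are pure mass-action with integer stoichiometry, and the
  one-hot invariant is assertable along any trajectory.
* **Transcription of the switch** is a single channel with compound
  propensity $r_0 S_0 + r_0 S_1 + r S_2$, keeping the six-way
  probability grouping aligned with the closed forms. $\tilde K$ and
  $b_1$ use this channel's actual propensity (so at $S_2$ the basal term
  is absent); the survival-vs-oracle agreement pins this convention.
* **Mean-field equations** are kept verbatim from their published form,
  including the quadratic self-binding term in the switch's
  $\dot{\bar S}_1$; at strong activation its fixed point pushes the
  reconstructed $\bar S_0$ slightly negative ($\approx -0.12$), a
  closure artifact that does not affect the saturation of $\bar m$ used
  in tests. (The mean-field route is diagnostic only; the simulators do
  not use it.)
* **Random numbers** in the compiled loops come from a splitmix64-seeded
  xoshiro256++ generator; realization $i$ of an ensemble with root seed
  $s$ uses the child stream seeded from
  $s \oplus \phi\,(i + \text{offset} + 1)$ ($\phi$ the 64-bit
  golden-ratio constant), so ensembles are reproducible,
  order-independent, and two arms of a comparison can share a root seed
  without sharing randomness (`stream_offset`).
* **Degenerate inputs**: $q = 0$ uses the linear-growth limit of
  $\lambda(t)$; $a = \tilde q$ uses the series limit; an all-silent
  simulated group returns a no-event sentinel and the analytic means
  relax freely; roundoff negatives of cascade means are clamped at zero.
* **Ties and edge draws**: uniform variates for waiting times are drawn
  from $(0,1]$ (so $\tau = 0$ is possible but $\log 0$ is not), and
  selection uses the strict cumulative rule, so zero-probability
  channels are never chosen.

## A short session

```{r example, eval = FALSE}
net <- switch_network()
hyb <- simulate_hybrid(net, t_final = 500, seed = 1,
                       record_times = seq(0, 500, 10), n_real = 1000)
ga  <- simulate_ssa(net, t_final = 500, seed = 1,
                    record_times = seq(0, 500, 10), n_real = 1000,
                    stream_offset = 1000)
cmp <- compare_ensembles(summarize_ensemble(hyb, c(150, 300)),
                         summarize_ensemble(ga, c(150, 300)))
cmp
```

The comparison object carries the per-grid-point $z$-matrices, their
maxima, and the histogram $\chi^2$ table; `write_comparison()` emits the
tab-separated report the command-line tool produces.

## Known limitations

* Only partitions whose analytic half is a linear (Poisson-solvable)
  cascade are supported; the two built-in models are the supported
  surface, and arbitrary user partitions are out of scope.
* The compiled oscillator loop accepts $d \le 10$; the closed-form
  incomplete-gamma evaluation loses accuracy slowly as $d$ grows past
  that.
* The exact-mode stepper is a validation tool; it re-integrates the
  lattice per step and is orders of magnitude slower than the
  production mode.
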
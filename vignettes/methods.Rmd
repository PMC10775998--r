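---
title: "Designing the thermodynamics-dynamics trade-off of IDP condensates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing the thermodynamics-dynamics trade-off of IDP condensates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpal)
```

## The scientific problem

Biomolecular condensates formed by intrinsically disordered proteins (IDPs)
have two families of properties that matter for their biology and for
materials design: thermodynamic stability (how strongly the chains attract
each other, hence how robust the condensed phase is) and internal dynamics
(how mobile the chains remain inside the condensate). For homopolymers these
two are strongly coupled: stronger attraction means slower chains. The
question this package addresses computationally is whether, and how far,
heteropolymer sequence design can decouple them.

`idpal` implements a multi-objective active-learning loop over short
polypeptide sequences (lengths 20 to 50): it learns surrogate models mapping
sequence features to a stability proxy and a dynamics proxy, proposes new
sequences by maximizing an expected-hypervolume-improvement acquisition with
a genetic algorithm, evaluates them with a pluggable property oracle, and
iterates until the Pareto front of the two proxies stops growing. The two
proxies are

* the second virial coefficient $B_2$, measuring net pairwise inter-chain
  attraction in dilute solution (negative = attractive; reported relative to
  the pervaded volume $V_0$ of an ideal chain), and
* the condensed-phase self-diffusion coefficient $D$ of a chain (reported
  relative to the Rouse scale $D_0$).

## The coarse-grained energy model

Chains are residue-level beads joined by harmonic bonds
$k_b (r - b_0)^2$ with $k_b = 10$ kcal/(mol·Å²), $b_0 = 3.82$ Å. Nonbonded
beads interact through an Ashbaugh–Hatch ("HPS") van der Waals term, a
Lennard-Jones potential whose attractive part is scaled by the mean
hydropathy $\lambda_{ij} = (\lambda_i + \lambda_j)/2$ and shifted so the
potential is continuous at $2^{1/6}\sigma_{ij}$, plus a Debye–Hückel screened
Coulomb term $q_i q_j e^{-r/\kappa} \, C/(D r)$ with dielectric $D = 80$ and
screening length $\kappa = 10$ Å (0.1 M ionic strength; the package's
`debye_length()` reproduces the 1 nm figure from first principles). The
Coulomb prefactor is folded into the single constant
$C = 332.0637$ kcal·Å/mol so all energies are in kcal/mol with distances in
Å. The per-residue parameters ($\lambda_i \in [0,1]$, diameters $\sigma_i$,
integer charges, masses; histidine neutral by default) ship as a plain-text
table (`inst/extdata/hps_urry_params.tsv`, the published HPS-Urry set) and
can be replaced by the user. No cutoffs are applied to analytic pair-energy
evaluation; cutoffs belong to simulation engines, which are out of scope.

```{r}
p <- load_parameter_table()
total_pair_potential(c(4, 6, 8, 12), "E", "K", p)
```

## Property engines

**$B_2$ from a potential of mean force.**
$B_2 = 2\pi\int_0^{r_{max}} r^2 (1 - e^{-\beta u(r)})\,dr$ is evaluated by
composite trapezoid quadrature on the PMF grid (default bin width 0.2 Å,
$r_{max} = 100$ Å). Non-finite $u$ is treated as hard core; a contiguous
hard-core prefix is integrated exactly up to the midpoint between the last
overlapping and the first finite grid point, which locates a step
discontinuity to second order — hard-sphere and square-well closed forms are
reproduced to better than 0.1% on the default grid. Beyond the grid the PMF
is taken as zero.

**Two-chain PMF by Monte Carlo.** For desk-scale work the package estimates
the center-of-mass PMF between two short chains ($N \le 10$ by default) from
the exact identity $u(r) = -k_BT \ln \langle e^{-\beta U_{inter}}\rangle$,
where the average runs over conformation pairs drawn from the isolated-chain
Boltzmann ensembles (Metropolis sampling of bonded plus intramolecular
nonbonded energy) at random mutual orientations and fixed COM distance. For
single beads this reduces exactly to the pair potential, which the test
suite exploits as an oracle. Per-bin uncertainties come from the delta
method on the log-mean-exponential.

**Phase separation from an equation of state.** A cubic spline is fitted to
pressure–density points; an interior negative dip (the finite-size van der
Waals loop) marks phase separation, and the condensed density $\rho_c$ is
the highest density at which the fitted pressure crosses zero, assuming a
near-zero coexistence pressure. Uncertainty comes from 50 Gaussian bootstrap
resamples of the per-point pressures; when the pressure is still negative at
the highest sampled density the condensed branch is flagged unresolved.

**Diffusion from mean-squared displacement.** $D$ is slope/6 of a linear fit
to the chain center-of-mass MSD averaged over chains and time origins. The
default fit window uses lags between 40% and 100% of one tenth of the
trajectory: at longer lags the time-origin averages decorrelate and the
statistical error of the MSD grows quickly, while shorter lags risk
contamination by sub-diffusive transients in real condensed-phase data. With
100 chains and 2000 frames this puts the estimator's statistical error near
1.5%, which is what the recovery tests assume. A log–log diagnostic slope
far from 1 (plateau or ballistic motion) triggers a warning.

**Reference scales.** $V_0 = (4\pi/3) b_0^3 (N/6)^{3/2}$ with $b_0 = 3.8$ Å
(the pervaded volume of an ideal chain) and $D_0 = \tau k_B T/(N \bar M)$
with $\tau = 1$ ps and $\bar M$ the mean residue mass. At $N = 50$ and 300 K
these evaluate to 5529 Å³ and $0.42\times10^{-9}$ m²/s. The Rouse argument
predicts $D \sim -N^{1/2} B_2$ for phase-separating homopolymers;
`homopolymer_scaling()` quantifies how well a record set obeys it and
whether the $N^{1/2}$ factor improves the correlation.

## Sequence featurization

Each sequence maps to a 30-dimensional vector: 20 composition fractions plus
ten chain-level descriptors — length $N$, mean hydropathy $\bar\lambda$,
sequence hydropathy decoration $SHD = N^{-1}\sum_{m>n}
(\lambda_m+\lambda_n)(m-n)^{-\beta}$ with $\beta = 1$, fractions of positive
and negative residues, absolute net charge per residue, sequence charge
decoration $SCD = N^{-1}\sum_{m>n} q_m q_n (m-n)^{1/2}$, a mean-field second
virial coefficient $B_2^{MF}$ (the $N^2$-weighted, composition-averaged sum
of single-bead pair virial integrals of the CG potential — an intentionally
crude orientation-free stand-in), the Shannon entropy of the composition
(natural log), and the mean residue mass. The SCD/SHD distance-kernel
exponents are arguments, since several conventions circulate in the
patterning literature; the defaults above are the most common. Negative SCD
marks blocky arrangements of opposite charges, positive SCD net-charge
dominance.

Descriptors are min–max scaled to $[0,1]$ with *fixed* physical bounds
(length window $[20, 50]$; patterning and $B_2^{MF}$ bounds computed once
from extremal sequences at $N = 50$ with a 10% margin) rather than
dataset-dependent scaling, so feature vectors remain comparable across
active-learning iterations; out-of-bound values are clamped with a warning.
Whether to min–max or z-score is a genuinely open choice; min–max was chosen
because fixed physical bounds exist for every descriptor, which
dataset-independent z-scoring would not give.

## Surrogates

Two Gaussian-process regressors predict standardized $\tilde B_2$ (trained
on all records) and $\tilde D$ (trained on phase separators only — $D$ is
undefined otherwise), and a random forest classifies phase separation. The
GP kernel is an isotropic squared exponential on the unit feature cube with
a fitted observation-noise term; hyperparameters maximize the log marginal
likelihood (Nelder–Mead over log-parameters). An isotropic kernel was chosen
over per-dimension relevance weights: the features are pre-scaled to a
common unit cube, and at desk-scale training sizes (tens to hundreds of
rows) a 30-parameter relevance search is poorly determined and slow. The
$\tilde D$ regression can optionally run on $\log D$ (`d_log_space`);
the default is the linear standardized scale. The classifier defaults to
500 trees; for the genetic algorithm's inner loop the fitted forest is
flattened to plain arrays and evaluated in compiled code, with exact
agreement against the reference predictor asserted in the tests.

## Acquisition

Candidate quality during the intermediate design rounds is the exact
two-objective expected hypervolume improvement over the current standardized
front (objectives $-\tilde B_2$ and $\tilde D$, both maximized, independent
Gaussian predictions), computed by a strip decomposition: with front points
sorted by the first objective and sentinel strips at the reference point,
the expected improvement factorizes per strip into a clipped first-objective
expectation times a second-objective excess expectation, each a closed-form
truncated-normal moment. The implementation is validated against
$10^5$-draw Monte-Carlo EHVI and reduces to the deterministic hypervolume
gain as the predictive spread vanishes. The $\Psi$ helper
$\Psi(a,b,\mu,\sigma) = (a-\mu)\Phi(\frac{b-\mu}{\sigma}) +
\sigma\phi(\frac{b-\mu}{\sigma})$ is checked against numerical quadrature.
The per-round EHVI reference point is the componentwise minimum of the
observed standardized objectives minus a 10% range margin.

The fitness schedule over iterations $k = 0, \dots, 8$ is

$$f(x) = \begin{cases} -\tilde B_2(x) & k = 0\\
\mathrm{EHVI}(x)\cdot \mathrm{RF}(x) \cdot \alpha(x) & 0 < k < 8\\
-\tilde B_2(x) + \tilde D(x) & k = 8\end{cases}$$

where $\mathrm{RF}$ is the hard classifier label (a candidate predicted not
to phase separate scores zero) and $\alpha \in [0,1]$ is a similarity
penalty: the harmonic mean of the cosine dissimilarities
$\tfrac12(1-\cos)$ between the candidate and all previously simulated
sequences plus the children already accepted in the current round. The
harmonic-mean form makes $\alpha \to 0$ whenever the candidate closely
resembles even one history entry, which is exactly the intended duplicate
suppression; an arithmetic mean would not have that property. An empty
history gives $\alpha = 1$. A narrower reading in which the history resets
every iteration was evaluated and performed measurably worse on the
synthetic benchmark (less diverse batches), so the broad history is the
default.

Pareto bookkeeping for convergence reporting happens in the *raw*
dimensionless plane $(-B_2/V_0,\ D/D_0)$ with a fixed reference point
(default $(10, 0)$): a dataset-dependent standardized plane would rescale
between iterations and destroy the monotonicity of the hypervolume trace
that convergence monitoring relies on. EHVI itself operates in the
per-iteration standardized plane as described above.

## Genetic algorithm

Children are produced by a greedy stochastic local search: starting from a
random parent (parents are the current Pareto sequences; in round 0, the
most attractive seed sequences), each step applies, independently and in
order, crossover (probability 0.5, single shared-cut prefix/suffix swap with
a random parent), point mutation (0.8), contiguous-segment deletion (0.2)
and in-place segment duplication ("growth", 0.5), with lengths kept in
$[20, 50]$ (an infeasible move is skipped). Acceptance is keep-if-better
with ties accepted at probability 1/2, for 100 steps. For each child,
`n_trials` independent searches run (batched through compiled move and
fitness kernels) and the best trial wins; duplicates of already accepted or
previously simulated sequences trigger a bounded number of re-runs before
falling back to the best fresh trial result. The package defaults are 96
children from 96 trials each, mirroring the full design protocol.

## The synthetic oracle and what it does (not) show

The oracle replaces molecular simulation so the full loop runs in minutes.
It maps three descriptors to ground truth through an attraction score
$a = \min\!\big(1, (0.45\,\bar\lambda + 0.35\,u + 0.4\,s)/0.9\big)$ with
$u = (N-20)/30$ and $s = \min(1, \max(0, -SCD)/2.5)$, then

* $B_2^{true}/V_0 = 10 - 60\,a^2$ (hydrophobicity, length and blocky
  opposite-charge patterning all deepen attraction; weakly attractive random
  sequences stay near zero or positive),
* phase separation iff $B_2^{true}/V_0 < -10$ (roughly a third of random
  disorder-biased sequences separate, so the classifier always sees both
  classes),
* for separators, $D^{true}/D_0 = 5\,(V_0/\!-\!B_2^{true})\sqrt{50/N}\,
  (1 + 1.5\,s)$: the homopolymer Rouse law times a patterning bonus that
  plants a heteropolymer advantage — at equal $B_2$, blocky polyampholytes
  diffuse up to 2.5 times faster than homopolymers, the synthetic analogue
  of the trade-off-breaking sequences the method is designed to find,
* condensed density $\rho_c = 0.3 + 0.7a$ g/ml.

Measurement noise is Gaussian on $B_2$ (sd $0.5\,V_0$) and 5% lognormal on
$D$; the phase flag is noise-free. All coefficients are explicit in
`oracle_config()`. Because homopolymers have $s = 0$, the noise-free oracle
puts them exactly on $D \propto (-N^{1/2}B_2)^{-1}$, which
`homopolymer_scaling()` recovers with correlation $-1$.

The planted Pareto front is obtained by brute-force enumeration of a
structured reference family (diblock $E^cK^c$ heads with W/G tails over a
grid of lengths, block sizes and tryptophan counts) under the noise-free
oracle. The family spans the descriptor extremes the oracle rewards, so its
nondominated set is a demanding recovery target; the loop may legitimately
exceed its hypervolume slightly by finding off-family sequences.

What passing the closed-loop test shows: the surrogates, acquisition, GA
and bookkeeping cooperate to find a planted trade-off frontier from noisy
data. What it does not show: anything about real condensate physics — the
oracle is a smooth three-descriptor map with none of the frustration,
finite-size effects or sampling noise structure of molecular simulation.

## Problem sizes used by the validation suite

The packaged validation study runs 20 independent campaigns of the full
9-iteration schedule with 64 disorder-biased seed sequences and a batch of
24 children from 24 trials per child (the package default of 96×96 is used
for single-batch contract tests with an inexpensive fitness). The study
asserts a median recovery of at least 90% of the planted front's
hypervolume, nondecreasing per-run hypervolume traces, and a
fraction-of-new-Pareto-points that falls toward zero by the exploitation
round. Monte-Carlo/exact comparisons use 20 seeds (PMF), 50 instances at
$10^5$ draws (EHVI), and 20 seeds of 100 chains (diffusion recovery).

## Numerical choices and degenerate inputs

* Quadrature: trapezoid on the native grid; hard-core prefixes integrated
  exactly to the midpoint; $u \equiv 0$ gives $B_2 = 0$ exactly.
* GP: jitter $10^{-8}$ on the kernel diagonal; predictive sd is the latent
  (noise-free) sd, which reverts to the prior far from data.
* EHVI at zero predictive sd follows the step-function limit (deterministic
  hypervolume gain); $\Psi$ at $\sigma = 0$ likewise.
* Ties on both objectives keep the first-seen point in the front;
  hypervolume excludes (with a warning) points that do not dominate the
  reference.
* Constant GA fitness: tie acceptance at probability 1/2 keeps the search
  mobile, and ties propagate the most recent state so degenerate landscapes
  still yield diverse, valid children.
* The similarity penalty returns exactly 0 for a candidate identical to a
  history entry and exactly 1 for an empty history.
* The EOS analysis errors on fewer than four density points and flags an
  unresolved condensed branch instead of extrapolating.

## Known limitations

* The two-chain Monte-Carlo PMF targets short chains (default cap $N = 10$);
  it is an illustration-scale estimator, not a replacement for biased
  sampling in a simulation engine.
* The mean-field $B_2^{MF}$ feature ignores chain connectivity and
  orientation correlations; it is a descriptor, not a property prediction.
* The GP is isotropic; with thousands of training rows and strongly
  anisotropic responses, per-dimension relevance would likely pay off.
* Real-data workflows must supply an external oracle (the property-table
  CSV interface or the oracle function contract); the packaged oracle is
  synthetic by design.
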
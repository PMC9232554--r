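---
title: "Models and methods behind cfpsflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cfpsflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfpsflow)
```

cfpsflow models cell-free transcription–translation (TX–TL) gene circuits
operated in microfluidic chemostats, and wraps that model in a
design–characterize–test workflow: simulate circuits under per-cycle DNA
inflow protocols, quantify which kinetic parameters the data can actually
pin down, search for inflow patterns that maximize parameter information,
fit shared parameters to a database of experiments as an ensemble, and
forward-predict new circuits built from the same parts. This vignette
records the model, its assumptions, the tunable parameters, and the design
choices made where the problem was genuinely open.

## The coarse-grained CFPS model

Each genetic construct (a linear DNA template) contributes three state
variables — template `DNA`, transcript `mRNA`, protein `P` — with
fluorescent reporters splitting their protein into a dark, immature pool
and the observable mature pool. For construct $i$ under dilution rate
$\lambda(t)$ and DNA inflow $k_{in,i}(t)$:

$$
\begin{aligned}
\dot{D}_i &= k_{in,i}(t) - \lambda D_i\\
\dot{M}_i &= \mathrm{TX}_i - (k_{deg,o(i)} + \lambda)\, M_i\\
\dot{P}_i &= k_{cat}^{TL}[o(i), riboj_i]\, M_i - \lambda P_i
\end{aligned}
$$

with, for reporters, $\dot{P}^{dark} = TL - (k_{mat}+\lambda)P^{dark}$ and
$\dot{P}^{mat} = k_{mat}P^{dark} - \lambda P^{mat}$. Transcription is

* linear for the constitutive sigma70 promoter,
  $\mathrm{TX} = k_{cat}^{TX,\sigma70} D$ (sigma70 is saturating and
  constant in the lysate);
* Michaelis–Menten in the sigma19 activator for p19a promoters,
  $\mathrm{TX} = k_{cat}^{TX,\sigma19} D\,\sigma_{19}/(k_d^{\sigma19} +
  \sigma_{19})$, with the *same* $k_d^{\sigma19}$ for bare and hybrid
  (operator-bearing) promoters;
* multiplied by a Hill repression factor
  $1/(1 + (R/k_d)^n)$ when an operator sits downstream of the
  transcription start. Repression acts on transcription, not translation
  (the RiboJ insulator decouples the operator context from the RBS).

Assumptions inherited from the experimental system: no resource
competition between genes; protein proteolysis is negligible relative to
dilution (chemostat outflow still removes protein); free sigma19 equals
total sigma19. Units are nM and minutes throughout; the catalytic
constants printed in nM·min⁻¹ are used as per-nM-template
(per-nM-transcript) turnover numbers of the same numerical value.

Reporter maturation rates are treated as known instrument constants, never
fitted: `kmat_deGFP = 0.06` min⁻¹ and `kmat_mmCherry = 0.015` min⁻¹,
typical literature values for these fluorophores at 30 °C; both are
configurable fields of the parameter set.

## Chemostat mechanics

The hardware replaces a fixed fraction RF (default 0.40) of the reactor
volume every cycle (default 22.5 min); 70% of the refreshed volume carries
lysate and energy solution, the rest DNA stocks and water. The control
variable is the matrix of per-cycle inflow fractions IF, one column per
construct, with row sums at most 1 within the DNA/MQ share.

Two dynamical readings of the same protocol are implemented behind one
contract (`protocol_to_controls`):

* **continuous** (default, used everywhere): within cycle $j$,
  $k_{in,i} = IF_{j,i}\cdot RF\cdot stock_i/T$ and
  $\lambda = RF/T$, both piecewise constant. This matches the ODE
  treatment of the system and integrates cleanly.
* **discrete**: instantaneous replacement
  $x \leftarrow (1-RF)x + RF\,u$ at each cycle start, reaction-only
  dynamics in between. The two agree at the common fixed point
  $D^\ast = IF\cdot stock$ and, after a burn-in of several cycles,
  their boundary values agree within a few percent at RF = 0.40; the
  transient differs (per-cycle decay 0.6 versus $e^{-0.4}\approx 0.67$),
  which is why the agreement is asserted on fixtures only after burn-in.
  Sequential within-cycle loading (lysate, then DNAs, then MQ) is not
  modelled.

Integration restarts at every cycle boundary so control discontinuities
are honored exactly (`deSolve::lsoda`, rtol 1e-8 / atol 1e-10 by default;
halving tolerances moves observables by less than 1e-6 relative).
Observations default to cycle boundaries — one image per cycle.

Working concentrations for the packaged experiments were chosen once as
realistic operating points: 10 nM template stocks held at 1 nM via
IF = 0.1, which leaves head-room in the DNA/MQ share for large pulses in
the same cycle. Pulses are specified by the concentration they deliver
(IF × stock), e.g. the 5 nM PhlF pulse of the pulse decoder and the
2 / 5 nM pulses of the bistable switch.

## Identifiability: collinearity indices

Relative output sensitivities $S_{t,\theta} = (\partial y_t/\partial
\log\theta)/\max(|y_t|, 10^{-9})$ are computed by central finite
differences on log-parameters (relative step 1e-4; agreement with a
ten-fold smaller step is ~1e-3, which is the accuracy claimed — no exact
sensitivity equations are solved). For a parameter subset, columns are
unit-normalized and the collinearity index is $\gamma = 1/\sigma_{min}$ of
the normalized submatrix, capped at 1e6; $\gamma = 1$ means orthogonal
(independently identifiable) directions, large $\gamma$ means the
parameters compensate for each other.

Two structural degeneracies of this model are worth knowing: (i) the
sigma19 branch enters every observable only through the combination
$k_{cat}^{TX,\sigma70} k_{cat}^{TL,\sigma19}/k_d^{\sigma19}$, so those
pairs sit at the cap in every design; (ii) within any single experiment a
repressor's translation rate and its $k_d$ enter only through their
ratio. Degeneracy (ii) is exactly what pooling RiboJ / no-RiboJ variants
breaks — the shared $k_d$ acquires two distinct translation columns — and
that mechanism is asserted numerically in the tests.

For the four-design comparison (batch dilution series, step flow,
optimized flow, full database) indices are computed per experiment,
category-lumped over \{K_TX, K_TL, K_reg, K_deg\}, averaged within a
scenario, and normalized to the batch scenario's maximum; only the
database scenario pools all 13 experiments into one sensitivity matrix
before the SVD, because its claim is precisely that the collection is
analysed as a whole. Lumping happens before averaging (lump-then-mean).
Under this computation the mean lumped index orders batch > step >
optimized > database on the TetR circuit, the qualitative signature of
information increasing along the workflow.

## Optimal experimental design

A design is an IF matrix (plus, optionally, stock concentrations within
bounds). Scores, higher-is-better: D-optimality
$\log\det(S^\top S + 10^{-12}I)$, or the negative mean lumped
collinearity. The goal is maximal information / minimal parameter
covariance, so the determinant of the Fisher information matrix is
**maximized** (equivalently, the covariance proxy $\mathrm{FIM}^{-1}$ is
minimized). IF values live on a discrete 5%-step grid mirroring load-step
hardware granularity; rows exceeding the DNA/MQ share are renormalized
and re-snapped. The search is an elitist population algorithm (row-wise
crossover, random-reset mutation, optional log-uniform stock mutation);
it is seeded, never returns less than the best initial member, and its
optimum is only as good as the nominal parameter estimate — re-scoring a
design at distant parameters can degrade it, which is tested as a
non-invariance. A robust mode averages the score over an ensemble of
nominal sets.

The packaged optimized IFFL pattern (`inst/extdata/
iffl_optimized_pattern.tsv`) was produced once by this search
(collinearity criterion, step-column nominal parameters, 32 cycles,
population 10, 160 evaluations) and is applied to every IFFL variant,
mirroring the workflow's single shared optimized pattern.

## Ensemble database fitting

All experiments are fitted simultaneously with globally shared parameters
(shared by name across networks). The objective is the sum of squared
residuals on mature-reporter traces, each observable normalized by its
observed maximum (the weighting is a package choice; reporters of
different brightness then weigh comparably), plus a soft biophysical
penalty: at flow steady state every activated construct must keep
$2 < [mRNA]_{ss}/[DNA]_{ss} < 500$; the penalty is a quadratic hinge
outside that band (zero at the boundaries within 1e-9), weight 10 by
default. Simulation failures score a large finite 1e8 so the population
search survives them.

The optimizer is differential evolution (DE/rand/1/bin, F = 0.7,
CR = 0.9) in log-parameter space inside hard bounds, optionally split
into islands with migration and stagnation restarts. The *ensemble* is
the archive of distinct agents from the later half of the generations,
filtered to within twice the best objective (at least 10 members kept):
along well-identified directions the archive is tight, along flat
(collinear) directions the population drifts and the archive records that
spread. This is deliberate — the method's output is a distribution of
plausible parameter sets, not a point estimate. Precision is summarized
as the distribution width, mean of the five highest over mean of the five
lowest values, averaged per category and normalized to a reference fit.

Prediction bands simulate the best-scoring quantile (default 25%) of the
ensemble and report the pointwise mean ± one standard deviation.
The RiboJ factor — the median ratio of with- to without-insulator
translation rates across characterized pairs — extrapolates translation
rates to parts never measured with the insulator.

## Reference parameter database

The package ships four reference parameter sets (means with bracketed
ranges used as hard fitting bounds): the individual step calibrations,
the pooled database, and the database updated with either prediction
circuit. Two curation notes: the step-column PhlF $k_d$ is printed with a
mean below its bracket in the source table, so its lower bound is widened
to the 1 nM used for the other repressors; and the mmCherry translation
rate is stored as the plain (no-insulator) rate, consistent with the
narrative that no RiboJ–mmCherry data existed and predictions required
multiplying by an inferred RiboJ factor. Translation rates of the
no-RiboJ repressor variants are not printed anywhere; the package derives
defaults as the RiboJ value divided by 2 (insulator-free translation is
generally weaker), a choice fixed once and flagged as package-derived.

## Prediction circuits

**Pulse decoder.** A four-stage repression cascade
(PhlF ⊣ CymR ⊣ TetR ⊣ deGFP) driven by sigma19. The system is
pre-equilibrated *without* the PhlF construct until every observable
changes by less than 1e-4 nM/min over a cycle; a PhlF inflow pulse of
duration $\Delta t$ then delivers 5 nM template, and the readout is
$a/b$: the post-pulse minimum of mature deGFP over a 450-min window
relative to the pre-pulse plateau. $a/b = 1$ at $\Delta t = 0$ by
construction and decreases monotonically with duration. The default
nine-duration grid spans 0–540 min in three-cycle steps: the cascade has
four dilution-limited stages of time constant $1/\lambda \approx 56$ min,
and by 540 min the response has reached its saturated floor (about 12% of
baseline at database means), so the grid covers the full range from no
response to saturation. Lowering the CymR construct from 0.5 to 0.1 nM
shifts the whole curve left, as less repressor needs to be displaced.

**Bistable switch.** Mutual repression between a CymR and a TetR
construct with two operator-gated reporters. The triple-switch schedule
establishes the CymR state (0.2 nM CymR construct, 16 cycles), adds the
TetR construct baseline (0.8 nM, 16 cycles), then applies three 3-cycle
pulses (5 nM TetR construct, 2 nM CymR construct, 5 nM TetR construct)
separated by 16-cycle settling phases — the mmCherry readout lags a state
flip by three to four dilution/maturation stages of roughly 60 min each,
so shorter settles truncate slow switches. State classification uses the sign
of the difference of the two reporters, each scaled by its own trajectory
maximum, with a ±0.1 hysteresis band; a switch is pulse-aligned when it
occurs within 360 min (one settling phase) of a pulse start. Screening parameter sets sampled
within the database bounds (log-uniform rates, uniform Hill coefficients)
shows that sets executing exactly three pulse-aligned switches concentrate
at low repressor Hill coefficients — most sampled sets flip once and
stay, or never establish two states. At the shipped "database + switch"
means the schedule executes a clean triple switch.

## Synthetic data

`generate_study` simulates any experiment registry at known true
parameters, samples at cycle boundaries, adds additive truncated Gaussian
noise with sd $= \max(\sigma_{abs}, \sigma_{rel}\cdot y)$ (defaults 5 nM
and 5%, applied to mature reporters only — the instrument observes
fluorescence), clips at zero, and is bit-reproducible from its seed. It
emulates the chemostat's sampling structure and noise scale but *not*
lysate batch-to-batch variation, sequential within-cycle loading, or
fluorescence calibration error; passing tests therefore demonstrate
correctness of the machinery and internal consistency of the method, not
accuracy on any particular wet-lab dataset.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, sizes
chosen as the smallest that exercise each claim: steady-state oracles use
60-cycle single-gene runs at rtol 1e-11; the design-comparison uses the
full 13-experiment registry for sensitivities; the ensemble-narrowing
benchmark fits a 4-experiment TetR quartet (24 cycles each, 6 free
parameters, 20 agents × 20 generations) against a single step
calibration; the bistability screen samples 2000 parameter sets at rtol
1e-6 (classification is threshold-based and does not need tighter
integration). Other constants: sensitivity denominators floored at 1e-9
nM; collinearity cap 1e6; D-score ridge 1e-12; DE keep-factor 2 with a
minimum of 10 ensemble members.

## Known limitations

* No resource competition: strongly loaded circuits will deviate.
* Finite-difference sensitivities only; agreement beyond ~1e-3 with exact
  sensitivities is not claimed.
* The discrete loading sequence within a cycle is not modelled; the model
  assumes inflow is available from the cycle start, which biases
  short-pulse responses slightly.
* Structural degeneracies (sigma19 branch; single-experiment
  kcat_TL/kd ratios) are reported at the collinearity cap rather than
  resolved; only richer designs or pooled variants break them.
* SBML export is not implemented; networks serialize to YAML.
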
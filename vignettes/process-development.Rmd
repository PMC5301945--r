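---
title: "Model-based process development for a C–H activation flow reaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based process development for a C-H activation flow reaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aziflow)
```

## The process and the model

`aziflow` models the palladium-catalysed C(sp³)–H activation of the
aliphatic secondary amine 3,3,5,5-tetramethylmorpholin-2-one (**1**) to the
corresponding aziridine (**2**) in segmented (slug) flow, and implements
the two process-development strategies built around that model: model-based
design of experiments (MBDoE) for rapid kinetic-model refinement, and
surrogate-based closed-loop target optimisation.

The mechanism is lumped into four steps over eight species:

* `j = 0` — **1** + Pd(OAc)₂ ⇌ **B**, the catalyst–substrate palladacycle;
* `j = 1` — **1** + HOAc ⇌ **1**·HOAc, off-cycle protonation by acetic acid;
* `j = 2` — **B** + **B** ⇌ **A**, the unreactive resting-state complex;
* `j = 3` — **B** → **2** + Pd(OAc)₂, the lumped C–H activation, which
  consumes one equivalent of the hypervalent-iodine oxidant
  stoichiometrically while being kinetically zero-order in it.

Each slug behaves as an ideally mixed isothermal batch reactor at its
dispersion-free centre, so the model is the set of mole balances
dc_i/dt = Σ_j ν_ij r_j with mass-action kinetics that are first order in
every participating species except the oxidant.  Temperature enters
through the reparametrised Arrhenius form

k_j(T) = k_j,ref · exp(−(E_a,j/R)(1/T − 1/T_ref)),  T_ref = 343.15 K,

which decorrelates k_j,ref from E_a,j around the reference temperature:
isothermal experiments at T_ref inform the rate constants alone, and
temperature-varied experiments then inform the activation energies.  The
default kinetic parameters are the study's fitted values; the DFT-derived
a-priori guesses are available via `azi_kinetics(initial_guess = TRUE)`.

## Thermodynamics: why the equilibrium constants are held fixed in T

Reverse rates are built from equilibrium constants via the van't Hoff
relation K_eq = exp(−ΔG/(RT)) with a-priori Gibbs free energies of
reaction (±7 kJ/mol accuracy).  Those free energies come without an
enthalpy/entropy split, so extrapolating K(T) = exp(−ΔG/RT) across the
40–110 °C operating window silently assumes ΔG is pure enthalpy — the
*strongest* possible temperature dependence.  The package's default
therefore evaluates every K_eq once at a fixed evaluation temperature
(`T_eval = T_ref`), i.e. treats the equilibria as temperature-independent
over the window; `azi_thermo(mode = "state")` restores the
enthalpy-like extrapolation for comparison.  This choice is not
cosmetic: with temperature-independent equilibria the model's
late-time yield ceiling is itself temperature-independent, which is what
lets a single calibration reproduce the study's identical predicted
yields (98.72 %) at two different operating points (107 °C/9 min and
101 °C/10 min).

## The calibrated network variant and its synthetic free energies

The published supplementary material (full mechanistic scheme, DFT free
energies, and the absolute concentrations behind the validation runs) is
not machine-readable, so the package carries two network variants:

* `azi_network("apriori")` — the irreversible lumped C–H activation,
  the structure the a-priori mechanism suggests.  Under it the model
  converges to essentially complete conversion at the validation
  conditions (≈ 99.999 %), not the published 98.72 %.
* `azi_network("calibrated")` (default) — identical except that `j = 3`
  is a strongly product-favoured but *finite* equilibrium.  The final
  state is then a genuine chemical equilibrium in which ~1.3 % of the
  substrate skeleton rests in **1**, **1**·HOAc, **B** and **A**, giving
  a yield ceiling of 98.72 % that both validation points reach.

The default free energies, ΔG = (−6.57, +10, −37, −8.935) kJ/mol for
j = 0…3, are **synthetic calibrated values**: ΔG₃ (and the ceiling) was
calibrated once against the two printed model predictions, ΔG₂ balances
resting-state visibility (it must shape the measured trajectories enough
for k₂,ref and E_a,2 to be estimable) against those same ceilings, and
ΔG₀/ΔG₁ are plausible magnitudes for the complexation and protonation
pre-equilibria.  They are *not* the study's DFT values and are labelled
synthetic wherever they appear.  The calibration was performed once,
before the downstream statistical machinery was evaluated, and is not a
tuning knob.

```{r validation}
x_a <- c(T_C = 107, t_min = 9,  c1_0 = 0.1, R_acid = 46.1, R_cat = 0.077)
x_b <- c(T_C = 101, t_min = 10, c1_0 = 0.1, R_acid = 41.4, R_cat = 0.077)
process_objectives(x_a)
process_objectives(x_b)
```

## The virtual laboratory

`run_virtual_experiment()` emulates the automated flow rig: a designed
slug is simulated and measured like the GC would — one product
concentration per sample time with additive Gaussian noise of
σ = 0.0005 mol/L, plus one pre-reaction substrate assay with
σ = 0.0003 mol/L.  The printed instrument "accuracy ± x" is read as one
standard deviation of a constant-variance Gaussian (a uniform half-width
variant is selectable); the noise is untruncated so the error model
stays unbiased near zero.  Experiments violating the rig's physical
limits — oxidant above its 0.3 mol/L crystallisation limit or
temperature above the 110 °C catalyst-decomposition limit — fail with
label −1 and return no measurements, exactly the information the
feasibility classifier consumes downstream.

What the generator does *not* emulate: slug dispersion and the
finite-width sampling it causes, drift or autocorrelation in the GC
response, day effects in catalyst activity, and model-structure error —
on real data the estimation residuals would not be independent
homoscedastic Gaussians.  Passing tests therefore demonstrate the
correctness and statistical calibration of the machinery under the
stated error model, not the adequacy of that error model for a
particular rig.

Design-space bounds (T ∈ [40, 110] °C, t ∈ [1, 60] min,
c₁,₀ ∈ [0.02, 0.2] mol/L, acid ratio ∈ [5, 60], catalyst ratio
∈ [0.01, 0.15]) bracket every printed operating point and are
config-overridable.

## Sensitivities, estimability and design-by-grouping

`local_sensitivities()` computes ∂c₂(t)/∂θ by central finite differences
(relative step 10⁻⁴; cheap, and directly checkable against an
independent difference oracle) and normalises by θ/max_t c₂(t), the
single measured output.  `estimability_rank()` flags parameters whose
normalised peak falls below 3·10⁻⁴ of the largest peak.  The threshold
was calibrated once: the off-cycle protonation parameters (k₁,ref,
E_a,1) sit 3–5 orders of magnitude below the largest peak — the step
equilibrates essentially instantly at k₁,ref ≈ 2.7·10⁶ L mol⁻¹ s⁻¹, so
the measured output carries no information about its *rate* — while the
weakest genuinely estimable parameter (E_a,2) sits near 5·10⁻⁴.  The
default separates the two populations with roughly a decade of margin on
either side.

`group_parameters()` clusters same-type parameters whose sensitivity
peaks fall within 20 % of the sampling horizon of each other
(single-linkage), the design-by-grouping heuristic that makes joint
designs tractable.

## D-optimal design and the two-step campaign

`fisher_information()` assembles FIM = Σ_k s_k s_kᵀ/σ² over a design's
sample times and `design_experiment()` maximises its log-determinant
over composition, sampling schedule, and (for step 2) temperature, by
multistart Nelder–Mead in a squashed unconstrained space.  Sampling
schedules are geometric (first time plus spacing ratio in (1.12, 2.5)) —
a two-parameter family spanning front-loaded to near-even schedules;
times closer than 0.5 min merge, and schedules that collapse below three
samples are rejected.  Designs must satisfy the rig feasibility rule
(the oxidant limit caps the substrate concentration at 0.15 mol/L with
the default 2 oxidant equivalents).

Direct calls to `design_experiment()` apply a practical-identifiability
floor: a design whose predicted relative standard error exceeds 10 for
any target parameter is infeasible, which is why designing for
{k₁,ref} fails outright.  The campaign planner
(`plan_two_step_campaign()`) relaxes the floor and instead applies the
published selection rule: among all combinations of single and grouped
estimable parameters it keeps subsets whose predicted t-values all
exceed the one-tailed 95 % reference quantile, preferring larger subsets
and breaking ties by the smallest maximum pairwise correlation from
FIM⁻¹; when nothing passes (typical under poor initial guesses) it keeps
every singleton plus the least-correlated grouped design.  The
t-convention is t_i = θ̂_i/(q·sqrt([FIM⁻¹]_ii)) with q the two-tailed
95 % quantile at dof = n − p; the published reference values imply a
different, unstated dof bookkeeping, which the package does not attempt
to reproduce.

## Estimation

`fit_kinetics()` minimises the weighted least-squares objective
Σ(observed − model)²/σ² by Levenberg–Marquardt in log-parameter space
(positivity for free), inside a ±3-decade box, with optional ±30 %
log-uniform multistart jitter.  Confidence intervals are Gauss–Newton:
the curvature of the residuals at the optimum gives a log-scale
covariance (eigen pseudo-inverted, so unidentified directions report
huge rather than failed intervals).  The printed report shows the
symmetric delta-method half-width ±q·θ̂·se_log; `confint()` returns the
asymmetric log-scale Wald interval θ̂·exp(±q·se_log), which is the
better-calibrated object for positivity-constrained, weakly identified
parameters — the Monte-Carlo coverage checks use it.  t-values reuse the
design-side convention.  `staged_estimation()` mirrors the study's strategy — each
experiment first refines only the parameters it was designed for
(processed in decreasing-sensitivity order, a continuation that stops
the weakly informed parameters from wandering), then all eight
parameters are fitted jointly, the practically unidentifiable j = 1 pair
included, whose confidence intervals then exceed their estimates by
orders of magnitude.

Numerical notes: during fitting the integrator runs at rtol 10⁻¹⁰ /
atol 10⁻¹² and the Jacobian uses a 10⁻⁴ relative step — the weakly
sensitive parameters move the output by ~10⁻⁵ mol/L, so looser settings
drown the gradient in integration error.  A failed integration inside a
fit returns a smooth penalty that pulls back toward the start instead of
a flat wall.

## Objectives and process economics

Yield is y = 100·c₂/c₁,₀ (%).  Product output is ṁ₂ = m₂/t (kg/h), and
the specific cost (£ h/kg) is
(cost_el·W_el + Σ_i cost_i·m_i,0)/ṁ₂ with the heating duty
Q = (Σn_i)·c̄p·(T − T₀) and W_el = Q/η_heat.  The study prints neither
prices, heat capacity nor the measured heating efficiency, so the
defaults are placeholders from current reagent list prices
(η_heat = 0.45, c̄p = 150 J mol⁻¹ K⁻¹, T₀ = 20 °C), with one documented
calibration: the palladium-acetate price (90 298 £/kg, within the range
of current list prices) was set once so the model's predicted cost at
the first validation point equals the printed 1.92 k£ h/kg.  Materials
priced per segment are the substrate, acid, catalyst, oxidant and the
solvent; both £ h/kg and k£ h/kg are reported since the study mixes the
two.

## The closed-loop target optimiser

`run_closed_loop()` is a multi-objective active learner over the 5-D
design space (T, t, c₁,₀, acid ratio, catalyst ratio): Gaussian-process
surrogates per target, binary GP feasibility classification, discrete
candidate evaluation, NSGA-II refinement, and target-tolerance stopping
(yield within 1.5 percentage points of 100 %, cost within 10 % of
2 108 £ h/kg; both checked on the *measured* outcome).

Design choices where the published description is silent:

* **Acquisition.**  The joint probability, under the GP predictive
  distributions, that every target lands inside its tolerance band;
  when every feasible candidate's probability is negligible the
  proposal falls back to the feasible candidate with the largest total
  predictive variance (pure exploration).  Ties break at the lowest
  candidate index.
* **Surrogates.**  Anisotropic squared-exponential kernel with constant
  mean; inputs min–max scaled to the unit cube, outputs standardised;
  cost modelled on the log scale since it spans decades over the design
  space.  Hyperparameters by type-II maximum likelihood with a
  conjugate-gradient optimiser; an ill-conditioned covariance gets
  jitter.
* **Classifier.**  Laplace-approximation GP classification with a
  logistic link over the ±1 feasibility labels; candidates with
  P(feasible) < 0.5 are excluded from acquisition, and single-class
  training collapses to a constant classifier.
* **NSGA-II refinement.**  Population 40 seeded in a ±5 %-of-range box
  around the proposal, 20 generations, SBX crossover and polynomial
  mutation, objectives |surrogate − target| (tolerance-normalised),
  classifier-infeasible points penalised; the refined point is accepted
  only if it does not worsen the scalarised tolerance-normalised
  distance, and the search is confined to that local box — refinement
  perturbs the proposal, it does not restart the global search.
* **Candidate pool.**  2 000 uniform points, fixed at initialisation
  under the run seed; already-evaluated points are excluded so the
  training set grows by exactly one unique point per iteration.

`run_optimisation("insilico")` trains on the model-development dataset
(every GC sample becomes one training point) and evaluates proposals on
the calibrated process model, then validates a successful recipe
through the noisy virtual lab; `run_optimisation("blackbox")` trains on
a 5-point Latin hypercube (`lhs_design()`, one point per stratum per
dimension) and evaluates directly on the noisy virtual lab.

## Problem sizes used in the tests

The packaged checks run the whole pipeline at desk scale, chosen as the
smallest sizes at which every statistical property is still sharply
testable: the reference campaign uses two design/estimate cycles with
3-start/30-iteration design searches (a fixed configuration seed, so the
campaign plays the role of the study's published design table);
confidence-interval coverage uses 50 Monte-Carlo noise replicates;
design quality is benchmarked against 100 random designs; and both
optimisation campaigns run 10 seeds with caps of 200 (in-silico) and 15
(black-box) evaluations, the published runs being one 174-iteration
in-silico campaign and one 5-training + 6-iteration black-box campaign.
The fixed-step RK4 oracle comparisons use a moderated protonation rate
constant: at its default value that step equilibrates on sub-microsecond
timescales, outside any explicit integrator's stability region at the
oracle's step size (the adaptive stiff solver handles it, which is the
point of using one).

## Known limitations

* The thermodynamic defaults and the finite C–H activation equilibrium
  are synthetic calibrations standing in for unavailable supplementary
  data; conclusions about the real chemistry should not be drawn from
  them.
* The cost model's prices are placeholders with one calibrated entry.
* Estimation recovers the six estimable parameters from
  informative-by-design campaigns; from the DFT a-priori guesses the
  joint landscape is multimodal and fits can settle in
  prediction-equivalent but parameter-distant optima (large confidence
  intervals flag this honestly, as in the study).
* The equilibrium ceiling makes the validation yields insensitive to
  the unknown absolute concentrations; that insensitivity is a property
  of the calibrated variant, not evidence about the real system.
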
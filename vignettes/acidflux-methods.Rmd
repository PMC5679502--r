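---
title: "Dynamic FBA of fungal organic-acid fermentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic FBA of fungal organic-acid fermentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidflux)
```

## The problem

*Aspergillus niger* batch fermentations produce citric acid in a
characteristic biphasic (diauxic) pattern: rapid growth while external
phosphate lasts, then a slow, phosphate-limited phase during which the
carbon not needed for growth is excreted as organic acid. External
phosphate is taken up far faster than growth consumes it and banked
intracellularly as polyphosphate; the diauxic shift coincides with
external phosphate depletion, and citrate production starts at the
shift. `acidflux` implements this picture as a dynamic flux balance
analysis (dFBA) with a *double optimisation* at every time-step, and
couples it to dynamic medium pH through polyprotic acid-dissociation
chemistry.

## The dFBA scheme

All external pools (biomass $B$ in gDW/L; glucose, xylose, phosphate,
stored phosphate and seven organic acids in mM; protons in mol/L) evolve
by explicit Euler steps

$$C_{n+1} = C_n + \Delta t \, f_n \, B_n,$$

where $f_n$ is the corresponding exchange flux (mmol gDW$^{-1}$
h$^{-1}$) returned by the FBA solve at step $n$ and $\Delta t = 1/60$ h
by default. Within a step the metabolic network is assumed at steady
state: $S v = 0$ over all non-boundary metabolites, with flux bounds
rebuilt from the current pools.

Each step solves two LPs:

1. **Growth**: maximise the biomass reaction. The explicit storage
   reaction is closed in this solve so that surplus phosphate uptake
   cannot masquerade as growth demand.
2. **Secondary objective**: growth is fixed from below at
   $\mu_{\max}(1-\delta)$ (default $\delta = 10^{-6}$, retried once at
   $10^{-3}$ if infeasible — fixing growth *exactly* is numerically
   brittle) and the secondary objective is maximised. The objective is
   chosen by a boolean on the step-1 solution: if the external phosphate
   influx sits strictly below its kinetic constraint (relative tolerance
   $10^{-6}$ plus an absolute guard of $10^{-9}$, see *Numerical
   choices*), spare uptake capacity exists and **net phosphate storage**
   (storage flux minus stored-phosphate release) is maximised; otherwise
   growth is phosphate-limited and **proton production** (the `Hpe`
   output) is maximised.

Citrate production is therefore *emergent*: nothing in the model
schedules it. It begins at the first step whose growth optimum saturates
the phosphate-uptake constraint, which the simulations place at external
phosphate depletion — about day 3 on the inoculation clock under the
default medium.

## Kinetic constraints

Uptake bounds are Michaelis–Menten forms in the external pools (rates in
mmol gDW$^{-1}$ h$^{-1}$, concentrations mM):

* external phosphate: $v_{Pe} = v_{Pe,\max} P_e / (K_{Pe} + P_e)$ with
  $v_{Pe,\max} = 0.08$, $K_{Pe} = 0.0333$; from 8 h after the simulation
  start the maximum drops to 0.015 (initial pH $\le 2$) or 0.004
  (initial pH $> 2$);
* stored phosphate release: $v_P = v_{P,\max} P/(K_P + P)$ with
  $v_{P,\max} = 8\times10^{-4}$, $K_P = 0.0833$ — this small cap *is*
  the phosphate-limited growth rate;
* glucose: passive diffusion $v_{G1} G$ ($v_{G1} = 3.1419\times10^{-4}$
  per mM) plus high-affinity facilitated transport
  $v_{G2,\max} G / [K_{G2}(1 + C/K_{i2}) + G(1 + C/K_{i2})]$,
  non-competitively inhibited by external citrate $C$; a low-affinity
  system of the same shape is added only while glucose $\ge$ 150 g/L
  (re-evaluated every step as the concentration falls). The inhibition
  factor is applied to both denominator terms, exactly as the transport
  model is stated, although this equals scaling the whole Michaelis term;
* xylose: the analogous two/three-term form without inhibition;
* glucose oxidase (GOX): the flux is *forced*, not optimised:
  $v_{GOX} = p_{GOX} \cdot 27.48\,[\mathrm{GOX}] \cdot G/(K_{GOX}+G)$
  with $p_{GOX} = -0.102\,\mathrm{pH}^2 + 1.082\,\mathrm{pH} - 1.95$
  clamped to $[0,1]$ (the raw quadratic is negative below pH $\approx$
  2.2 and must never generate a negative rate). Gluconate and its
  protons are therefore produced independently of the proton objective.

Secretion caps: citrate 0.12 if the culture *started* at pH $\le 2$,
0.016 otherwise; oxalate 0.01, forced to 0 whenever the *current* pH is
strictly below 2. The 150 g/L thresholds are converted to mM with molar
masses 180.16 (glucose) and 150.13 (xylose); threshold comparisons are
strict as worded ("below", "greater than or equal to").

## Acid dissociation and pH

Each secreted acid releases a pH-dependent number of protons per mole,

$$H \;=\; \frac{K_1 H_e^{-1} + 2K_1K_2 H_e^{-2} + 3K_1K_2K_3 H_e^{-3}}
              {1 + K_1 H_e^{-1} + K_1K_2 H_e^{-2} + K_1K_2K_3 H_e^{-3}},$$

the average charge of the equilibrium speciation (absent sites enter as
$K=0$). The engine rewrites the proton coefficient of every
acid-dissociation reaction at the step-start pH (fractional
stoichiometry), so "maximise proton output" automatically reflects the
ambient pH and the acid hierarchy it induces: per carbon atom, oxalate
is the most efficient acidifier over a wide pH range, citrate second at
low pH. Protons are accumulated into $H_e$ by the same Euler update
(divided by 1000 for mmol $\to$ mol) and $H$ is held at its step-start
value within a step. No buffering is modelled — the medium's urea and
trace CaCO$_3$ are ignored, which is our documented assumption — and
$H_e$ is floored at $10^{-14}$ M.

## The toy network

The bundled fixture (`make_toy_network()`, also shipped as TSV and SBML
under `inst/extdata/`) is a deliberately minimal, hand-checkable network:
24 metabolites, 23 reactions, one internal carbon-unit currency (glucose
contributes 6 units, xylose 5). Biomass synthesis consumes carbon units
with a 5$\times$ respiratory overhead (4 carbons respired to CO$_2$ per
carbon fixed; biomass yield $\approx$ 0.18 g/g glucose, in the plausible
range for acidogenic cultures) plus phosphate according to a fungal-style
composition (42% protein, 40% carbohydrate, 3% phospholipid, 2% nucleic
acid, 5% glycerol, 8% ash). The composition implies 0.10 mmol P/gDW,
chosen once so that the default world reproduces the empirical timeline:
carbon-limited growth at $\mu \approx 0.10$ h$^{-1}$ on 160 g/L glucose,
a storage phase that survives the 8-h uptake-rate switch, phosphate
depletion near day 3, then phosphate-limited growth at $\mu \approx
0.008$ h$^{-1}$. Real *A. niger* biomass carries several-fold more
phosphorus; with the uptake kinetics above, a realistic phosphorus
content would make growth phosphate-limited from the start and destroy
the diauxie. This is a deliberate property of the desk-scale world, not
a fitted value.

Every one of the seven acids has a secretion/dissociation pair with the
correct carbon count (6,2,6,2,4,4,3); the four minor acids (acetic,
malic, succinic, lactic) ship with secretion bounds of zero — the
organism does not secrete them in these fermentations, and in a toy
network without cofactor/energy costs the proton objective would
otherwise happily excrete whichever acid has the best protons-per-carbon
ratio. Oxalate is produced by the `OAH`-tagged reaction (closed by the
*oah* knockout), gluconate by the extracellular `GOX`-tagged reaction
(forced flux; zeroed by the *gox* knockout). The biomass-equation
adjustment scales the nucleic-acid and phospholipid mass fractions and
recomputes the glycerol fraction so total mass is conserved, then
rebuilds the biomass reaction's carbon/phosphate coefficients.

**What a green test establishes — and what it does not.** The toy world
demonstrates the *mechanisms*: the decision boolean, the emergent
diauxic switch synchronous with phosphate depletion, cap-limited acid
secretion, knockout behaviour, conservation, and the fitting machinery.
It does not reproduce the paper-scale titres or any genome-scale
redundancy (alternative pathways, cofactor balancing, maintenance ATP),
and quantitative agreement with published fermentation curves is out of
its reach by construction.

## Numerical choices

* **LP solver**: a bounded-variable two-phase primal simplex with
  Bland's rule (C++), fully deterministic — identical inputs give
  identical flux vectors. All bounds are finite (default magnitude 1000),
  so no LP is unbounded. Validated against an independent exhaustive
  vertex-enumeration oracle (`lp_vertex_oracle()`), which presolves
  chains of degree-2 metabolites and enumerates all basic solutions.
* **Decision boolean**: the spec-level relative tolerance ($10^{-6}$)
  is supplemented by an absolute guard of $10^{-9}$ mmol gDW$^{-1}$
  h$^{-1}$: the external phosphate pool decays exponentially and its
  uptake cap reaches $10^{-20}$, where a relative comparison of two
  solver outputs is meaningless noise.
* **Pool depletion**: every uptake bound is additionally capped by
  `pool/(B dt)` *before* the LP, so the optimiser can never overdraw a
  pool within a step and the per-step mass balances close exactly; no
  post-hoc flux truncation is needed in practice (a guard errors if a
  pool ever goes negative beyond rounding).
* **Flux dust**: fluxes below $10^{-11}$ are zeroed before the Euler
  update so simplex rounding (order $10^{-17}$) cannot seed pools that
  must stay identically zero (e.g. oxalate under $\Delta$*oah*).
* **Degenerate optima**: alternate optimal vertices are accepted; only
  objective values and tracked exchange fluxes are part of the package's
  guarantees. During the proton phase the storage reaction is closed
  (and vice versa the storage objective subtracts stored-phosphate
  release), so store/release cycles cannot appear in the reported fluxes.
* **Convergence**: the explicit Euler scheme is first-order, and the
  suite verifies order $\ge 0.8$ by Richardson comparison on the smooth
  early window. Threshold events (the 150 g/L switch, the diauxic
  switch) are quantised to the step grid; their $O(\Delta t)$ sawtooth
  makes single-endpoint Richardson ratios oscillate after an event even
  though the error still shrinks, which is why the test anchors before
  the first event.

## Fitting and model selection

`fit_parameters()` minimises a weighted residual sum of squares between
a simulated trajectory (linearly interpolated at the observation times)
and observations, over bounded parameters mapped to the real line by a
logistic transform. Mixed units are reconciled by per-variable weights,
by default the inverse squared range of each variable's observations.
One-dimensional fits use a deterministic 12-point grid scan followed by
Brent refinement in the bracketing interval — plain golden-section
search provably stalls on the plateau that appears once a secretion cap
stops binding. Higher dimensions use seeded multi-start Nelder–Mead.
Model variants are ranked by $\mathrm{AIC} = 2k + n\ln(\mathrm{RSS}/n)$
with no small-sample correction, matching the selection workflow the
method was published with. Fits may pool several experimental scenarios
(e.g. three initial phosphate levels fitted jointly, mirroring the
multi-level design of the original 84-point dataset); observations then
carry a `scenario` column.

The synthetic-observation generator emulates daily shake-flask sampling:
every 24 h on the inoculation clock, additive Gaussian noise (default SD
2% of each variable's trajectory maximum), floored at zero. It does not
emulate replicate structure, autocorrelated assay errors, or
variable-specific error models. Identifiability is design-dependent:
$K_{Pe}$ (0.0333 mM) only acts in the narrow depletion window, so
single-run daily sampling leaves it with estimator spread beyond 15% at
2% noise even though noiseless recovery is exact; the pooled three-level
design sharpens it decisively. Likewise the GOX loading is only
identifiable from runs started at high pH (the activity polynomial is
zero at pH 2).

## Decisions on open questions

* The low-affinity sugar term is re-evaluated every step and switches
  off when the concentration falls back below 150 g/L.
* The passive-diffusion coefficients are treated as mmol gDW$^{-1}$
  h$^{-1}$ per mM of sugar.
* Growth in step 2 is a lower bound with slack, not an equality.
* Stored phosphate has no capacity limit, and the late-fermentation
  phosphate release upon carbon depletion reported empirically has no
  model rule — it is not implemented.
* The medium is unbuffered.
* With a carbon-free storage reaction (the storage objective is a pure
  phosphate translocation, as in the published model), a zero-carbon
  culture still stores phosphate even though growth and proton
  production are zero.

## Known limitations

Morphology/pellet effects, oxygen transfer, Mn$^{2+}$ sensitivity and
fed-batch policies are out of scope. One acceptance property fails
honestly in the toy world: at initial pH 7 the citrate titre of a
$\Delta$*oah* strain is not $\ge$ the control's, because citrate is
cap-limited in both strains (equal to first order) and a second-order
feedback — without oxalic-acid protons the culture stays above the GOX
inactivation pH longer, wasting more glucose on gluconate and slightly
shortening the high-growth phase — tips the comparison by about 0.8% the
wrong way. The double knockout $\Delta$*oah*$\Delta$*gox* removes that
channel and produces 59% more citrate than the control, matching the
published direction.
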
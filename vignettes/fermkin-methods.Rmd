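---
title: "Modelling fermentative metabolism under enforced ATP demand: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fermentative metabolism under enforced ATP demand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science and the design decisions behind
`fermkin`: what the kinetic model contains and assumes, how its default
parameter set was constructed, how the steady-state, control-analysis and
flux-analysis machinery works numerically, what the synthetic-data generator
does and does not emulate, and where the package's answers should and should
not be trusted.

## The biological setting

Overexpressing the soluble F1 subunit of the FoF1-ATP synthase forces
*E. coli* to hydrolyze ATP at a rate controlled by the expression level of
the construct. Measured panels of low-, medium- and high-copy expression
strains show that glucose uptake rises with moderate ATP wasting and
collapses under extreme wasting, together with a monotonically falling
adenylate energy charge, accumulation of hexose phosphates, and a switch of
fermentation towards lactate at the highest expression level. The package
implements the model-based analysis of this phenotype.

## The kinetic model

### Network

The model describes anaerobic central fermentative metabolism: PTS-mediated
glucose uptake, Embden-Meyerhof glycolysis at single-reaction resolution,
the fermentative branches to ethanol (ACDH/ADH via acetaldehyde), acetate
(PTA/ACK via acetyl-phosphate), formate (PFL), lactate (LDH) and succinate
(PPC/MDH/FHD/FRD with menaquinone-coupled fumarate reduction), PEP
carboxykinase as the reversible counterpart of PEP carboxylase, a lumped
CS/ACO/ICDH step to alpha-ketoglutarate, transhydrogenase, adenylate kinase,
a biomass (growth) reaction draining eight precursors plus NADPH and ATP,
a non-growth-associated maintenance reaction (NGAM), and the ATPase
reaction whose vmax is the scanned expression knob.

The model comprises 33 metabolites and 28 reactions. Of the 33 species, 27
are dynamic ODE states; external glucose and the five secreted products are
clamped boundary species, the standard treatment when analysing
intracellular steady states of exponentially growing or arrested cells.
Note that a network with only 28 reactions cannot support a
multi-dimensional steady-state flux space if all 33 species were dynamic
(the rank of the stoichiometric matrix would force v = 0), so the boundary
partition is not merely conventional but structurally necessary.
CO2 and inorganic phosphate are omitted entirely: they appear in no shipped
rate law, and clamping them would have the same effect as omission.
The transhydrogenase was added to close the NADP(H) balance, because the
biomass NADPH demand exceeds what the lumped isocitrate dehydrogenase step
supplies. Five conserved moieties are detected and verified against the
left null space of the stoichiometric matrix: ATP+ADP+AMP, NAD(H), NADP(H),
CoA+acetyl-CoA, and menaquinone/menaquinol.

### Rate laws

Every reaction uses convenience kinetics: saturable Michaelis-Menten terms
per reactant, multiplied by independent hyperbolic activation
(c^h/(Ka^h+c^h)) and inhibition (Ki^h/(Ki^h+c^h)) terms. Reversible steps
(PGI, FBA, TPI, GHD, PGK, PGM, ENO, PTA, PCK, MDH, FHD, NDH, THD, ADK) use
the reversible convenience form with a scaled equilibrium constant.
Allosteric regulation follows the canonical map for this pathway: ADP
activates and PEP inhibits PFK, PEP inhibits FBA, FBP activates PYK, G6P
feedback-inhibits the PTS, malate feedback-inhibits PPC, and
alpha-ketoglutarate product-inhibits the lumped CS/ACO/ICDH step. Model
version 2 adds exactly two terms: an ATP-dependent hyperbolic modulation of
the PFL vmax, g(ATP) = gmin + (1-gmin)·ATP/(Kg+ATP) with gmin = 0.05 and
Kg = 1 umol/gDW (low ATP means less PFL enzyme), and a pyruvate inhibition
of PYK (Ki = 2 umol/gDW, Hill 2).

Units: intracellular concentrations are umol/gDW, fluxes mmol/gDW/h;
the factor 1000 between them is applied once, at the ODE right-hand side.
External glucose is carried in mM and enters only through the PTS Km.

### The default parameter set

The published model's more than one hundred rate-law parameters are not
printed anywhere, so the shipped defaults are a synthetic, documented set
constructed in three steps:

1. **Reference state.** A wild-type steady state is fixed: concentrations at
   measured magnitudes (including the PFK working point PEP 0.27, F6P 0.91,
   FBP 9.74 and ATP+ADP = 2.67 umol/gDW; energy charge 0.90), and fluxes
   derived by propagating the measured wild-type growth rate (0.476/h),
   glucose uptake (13.48), lactate (0.83) and succinate (1.77 mmol/gDW/h)
   through the exact network balances. Ethanol and acetate fluxes follow
   from the NADH and acetyl-CoA balances rather than being imposed, so that
   N·v = 0 holds to machine precision.
2. **Affinities.** Michaelis constants are set relative to the reference
   concentrations (typically at or below the reference level, giving
   saturations of 0.5-0.9); allosteric constants are placed so that the
   regulation has headroom at the reference (e.g. the PFK ADP activation
   sits at 0.22 of its range, Ka = 0.8 umol/gDW, Hill 2). Reversible steps
   carry a "drive" (net/forward flux fraction); PGK is nearly at
   equilibrium (drive 0.05), which is what makes its flux control vanish.
   PCK and ADK are poised exactly at equilibrium at the reference, with a
   fixed exchange capacity.
3. **Calibration.** Every remaining vmax is computed so that the reference
   state is an *exact* steady state. This replaces iterative parameter
   fitting: the data enter through the reference state, and the model is
   exactly consistent with it by construction.

A few parameters implement deliberate qualitative behaviour rather than a
measured number, and are worth naming. The ATPase ATP dependence is
cooperative (Km 0.4 umol/gDW, Hill 3, consistent with the three-site rotary
mechanism of the F1 head); this makes the hydrolysis demand vanish faster
than the glycolytic supply as ATP falls, which is what stabilizes a live
(non-extinct) steady state on the whole scanned range and produces the
interior maximum of the ATPase flux. The NGAM and growth ATP terms are
likewise cooperative (Hill 2), encoding that maintenance and biomass
synthesis shut down below a threshold energy level; without these cutoffs
the model has an absorbing "dead" state that the scan falls into. The
growth reaction's precursor terms are nearly saturated at the reference so
that growth is controlled by energy, not by precursor supply. The biomass
ATP coefficient (40 mmol/gDW, growth-associated maintenance included) sets
the wild-type NGAM residual to 13 mmol/gDW/h, giving the maintenance
reaction a realistic share of total ATP turnover; this share determines how
strongly maintenance perturbations propagate into uptake.

### Steady states and scans

`steady_state()` first attempts a damped Levenberg-Marquardt Newton
iteration in log-concentration space on the moiety-reduced coordinates
(one dependent species per conserved pool is eliminated), which succeeds
whenever a nearby steady state exists — in particular along continuation.
If Newton fails, the stiff ODE is integrated with `lsoda` over
geometrically growing horizons and re-polished; for oscillatory regimes a
final Newton start from the cycle average usually lands on the interior
steady state. The steady-state tolerance is max |N v| <= 1e-8 mmol/gDW/h;
initial states must be strictly positive and match the conserved-moiety
totals to 1e-6 relative (or be renormalized on request). Non-convergence is
flagged on the returned object, never raised as an error.

`scan_atpase()` walks the vmax grid (default 0 to 85 mmol/gDW/h in steps
of 1) by continuation from the previous steady state. The response curve
has a genuinely steep transition between the high-uptake and collapsed
branches; the continuation tracks it without non-converged points at the
default step. Biphasy of a discrete curve is declared only when the
maximum is interior *and* the terminal value sits at least 5% below it,
so that plateaus do not count. The ADP-activation clamp evaluates the PFK
activation term once at the vmax = 0 steady state and freezes it for all
scan points, exactly the counterfactual that removes the biphasic uptake
response.

### Control analysis and Monte Carlo sampling

Flux control coefficients are computed from the elasticity matrix via the
matrix relations on the moiety-reduced system,
C = I − eps L (N_R eps L)^{-1} N_R, scaled by the steady-state fluxes;
rows belonging to near-zero fluxes are reported as NA. Because every rate
law is homogeneous of degree one in its vmax, the scaled coefficients of
each flux sum to one — this summation theorem is verified in the tests for
every Monte Carlo sample, and the matrix-method coefficients are
cross-checked against a finite-difference oracle that re-solves perturbed
steady states.

The Monte Carlo procedure multiplies every Michaelis constant by an
independent factor 10^U(-1, +1) (two orders of magnitude), then rescales
each reaction's vmax so that its rate at the reference concentrations
reproduces the reference flux exactly; equilibrium-poised reversible steps
have their scaled equilibrium constant re-derived instead. The reference
steady state is therefore a steady state of every sampled model by
construction. Allosteric constants are left at their fitted values — the
sampling probes the uncertainty in the saturation parameters, not the
regulatory structure itself. Draws under which the preserved steady state
loses dynamic stability (positive real part in the reduced Jacobian
spectrum) do not represent consistent alternative parameterizations of an
observed (hence stable) metabolic state and are rejected and redrawn; the
rejection count is reported on the result.

Reference states for the low/medium/high-copy strains are chosen as the
scan grid points whose steady-state uptake is closest to each strain's
measured uptake, with LC/MC matched on the ascending branch and HC on the
descending branch beyond the peak — the measured phenotypes themselves
say on which side of the peak each strain operates. The enzyme-doubling
predictions re-solve the steady state with a doubled vmax from the
reference state and report the new uptake.

## Metabolic flux analysis

The stoichiometric module is deliberately separate from the kinetic model:
a lumped reconstruction of the same pathway (glycolysis partially lumped,
both PEP carboxylase and a split reversible PEP carboxykinase, the
fermentative branches, a biomass reaction, CO2 exchange in both directions,
and the ATPM pseudo-reaction hydrolyzing ATP). Reconciliation minimizes the
SD-weighted squared adjustment of the measured rates subject to steady
state and non-negativity (a quadratic program with a 1e-8 ridge for strict
convexity; SDs are floored at 1e-3 to keep weights finite). ATPM
maximization is a linear program with the reconciled rates fixed as
equalities; linearly dependent equality rows (cofactor pairs, overlaps
between fixed exchanges and balance rows) are removed by QR factorization,
and a capped objective guards against energy-generating cycles. When the
simplex solver fails on degenerate vertices, a regularized quadratic
program (vanishing quadratic term) computes the same optimum.

The published flux analysis uses an 83-reaction stoichiometry that is not
printed; absolute ATPM values from the reconstruction here are therefore
comparable in magnitude, not identical. The one free coefficient, the
growth-associated ATP demand of the biomass reaction (default
75 mmol/gDW), was calibrated once so that the control strains' ATPM lands
at the non-growth maintenance scale estimated from the same kind of data;
it absorbs all ATP costs of growth that a lumped central-carbon
reconstruction cannot represent explicitly. The ATPase flux of an
overexpression strain is the ATPM difference to its control — an identity
that holds exactly for the published tables wherever those tables are
internally consistent, and is applied to model-computed ATPM values in the
end-to-end pipeline.

## Synthetic data

The generator emulates what the rate arithmetic assumes: exponential growth
(X = X0 e^{mu t}) or constant-biomass arrest, constant specific rates,
closed-form metabolite trajectories, glucose clamped at zero after
exhaustion with all rates ceasing, multiplicative lognormal noise on
biomass (default 2%, OD-like) and additive truncated-Gaussian noise on
concentrations (default 0.1 mmol/l, HPLC-like). Strain profiles are
calibrated to the measured rate tables shipped with the package, so a
noiseless round trip through the estimators recovers the published rates to
numerical precision, and noisy round trips are tested against the
analytically propagated estimator error.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: rates that drift within the sampled window
(real cultures leave balanced growth), correlated replicate errors,
sampling-time jitter, analyte-specific HPLC error structure, and the minor
residual growth observed in real nitrogen-starved cultures. The generator
validates the estimators and the pipeline plumbing, not the biology.

## Problem sizes and determinism

The shipped analyses use the sizes at which the results are stable: scans
at grid step 1 (86 steady states per curve), Monte Carlo sampling at
n = 200 with a fixed seed (sign fractions need only modest n; the headline
fractions move by about a point between seeds), and three replicates per
synthetic strain. All stochastic entry points take explicit seeds and are
reproducible call-by-call.

## Known limitations

* The default parameters are a plausible synthetic set, not the deposited
  fit; quantitative curve positions (peak location, terminal uptake) are
  model properties of *this* parameterization. The qualitative structure —
  biphasic uptake, monotone energy charge, interior ATPase-flux maximum,
  its disappearance under the ADP-activation clamp, the control-coefficient
  signs — is what the package asserts and tests.
* Version 2 reproduces pyruvate and PEP accumulation at high ATPase
  levels, but not the measured FBP accumulation; in both model versions
  FBP falls on the collapsed branch. The same qualitative gap motivated
  regulatory extensions in the original analysis, and closing it would
  require regulation beyond the two version-2 terms.
* The steep transition between the high-uptake and collapsed branches
  behaves like a fold: between neighbouring grid points the curve can jump.
  Within-step structure (e.g. possible bistability) is not resolved; if it
  matters, refine the grid locally.
* The stoichiometric reconstruction has no respiratory chain and is valid
  for anaerobic scenarios only; aerobic rate tables would require a
  different model.
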
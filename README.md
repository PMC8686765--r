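# fermkin

Kinetic and stoichiometric analysis of *Escherichia coli* central metabolism
under enforced ATP demand.

When the ATP-hydrolyzing F1 subunit of the FoF1-ATP synthase is overexpressed,
*E. coli* wastes ATP at a rate set by the expression level. Measurements on
strains with low-, medium- and high-copy expression plasmids show a striking
biphasic response: the specific glucose uptake rate first **rises** with the
ATP drain (the cell compensates with a higher glycolytic flux) and then
**collapses** below wild-type levels once a critical ATPase level is exceeded.
`fermkin` provides the computational machinery to analyse this phenomenon:

* a **kinetic model** of anaerobic central fermentative metabolism
  (33 metabolites, 28 reactions; convenience kinetics with allosteric
  regulation). The mechanistic core is the dual dependency of
  phosphofructokinase (PFK) on ATP as substrate and ADP as allosteric
  activator,

  v_PFK = vmax · sat(F6P) · sat(ATP) · [ADP²/(Ka²+ADP²)] · [Ki²/(Ki²+PEP²)],

  which makes the isolated PFK flux biphasic in the ADP fraction
  ADP/(ATP+ADP) and the whole-network glucose uptake biphasic in the ATPase
  expression level. Two model versions are provided; version 2 adds an
  ATP-dependent modulation of the PFL level and a pyruvate inhibition of
  pyruvate kinase.
* **steady-state scans** over the ATPase expression knob
  vmax(ATPase) = 0…85 mmol/gDW/h, including the counterfactual in which the
  ADP-activation term of PFK is clamped at its wild-type value (the biphasy
  disappears).
* **Monte Carlo metabolic control analysis**: flux control coefficients
  C^J_e = (e/J) ∂J/∂e from the elasticity matrix relations on the
  moiety-reduced system, with Michaelis constants resampled over two orders
  of magnitude while preserving the reference steady state exactly, and
  sign-dominance summaries of the sampled coefficient distributions.
* **metabolic flux analysis**: SD-weighted reconciliation of measured
  exchange rates (quadratic program) followed by linear-programming
  maximization of the ATP-maintenance (ATPM) pseudo-flux; the ATPase flux of
  an overexpression strain is the difference between its ATPM and that of
  its control.
* the **experimental rate arithmetic** (growth rates by log-linear
  regression, specific exchange rates for growing and growth-arrested
  cultures, yields by regression, percent changes, cumulated carbon yields)
  and a **synthetic-data generator** producing fermentation time courses
  with realistic noise from strain profiles calibrated to the measured rate
  tables (shipped in `atpase_exchange_rates()` and friends).

## Worked example

```r
library(fermkin)

m <- build_model(version = "v1")
m
#> Kinetic model of anaerobic central fermentative metabolism (v1)
#>   33 metabolites (27 dynamic, 6 boundary), 28 reactions
#>   conserved moieties: adenylate, nicotinamide, nicotinamide_p, coenzyme_a, menaquinone
#>   vmax(ATPASE) = 0 mmol/gDW/h

scan <- scan_atpase(m, seq(0, 85, by = 1))
scan
#> ATPase expression scan, 86 points on [0, 85] mmol/gDW/h
#>   glucose uptake: 13.48 at vmax 0, peak 17.14 at vmax 34, terminal 0.82
#>   ATPase flux peak 32.17 at vmax 48
#>   energy charge: 0.895 -> 0.122
```

The wild type (vmax = 0) takes up 13.48 mmol glucose/gDW/h at an adenylate
energy charge of 0.90; uptake peaks at 17.1 at an intermediate ATPase level
and collapses far below the wild type at maximal expression, while the
energy charge decreases monotonically. The ATPase flux itself peaks at an
interior expression level — the strain with the most ATPase hydrolyzes the
least ATP, because it has run itself out of substrate.

```r
wt <- steady_state(m)
samp <- sample_preserving_steady_state(m, wt, n = 200, seed = 1)
sign_dominance(samp, "PTS", "NGAM")[["positive"]]
#> [1] 0.97
```

97% of the sampled parameterizations agree that raising the maintenance ATP
demand *increases* glucose uptake at the wild-type operating point — the
ascending limb of the biphasic curve is a robust model property, not a
parameter accident.

```r
sm <- default_stoich_model()
est <- estimate_atpase_flux(sm,
  c(mu = 0.197, glc = 17.70, eth = 15.63, ace = 14.90, "for" = 30.24, lac = 0.84, suc = 1.66),
  c(mu = 0.461, glc = 15.02, eth = 10.51, ace = 10.93, "for" = 21.21, lac = 0.98, suc = 1.85))
est$atpase
#> [1] 24.71
```

From the measured exchange rates of the medium-copy ATPase strain and its
control, the reconstruction estimates an enforced ATP hydrolysis of
24.7 mmol/gDW/h (the published flux analysis of the same rates reports
25.45).

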
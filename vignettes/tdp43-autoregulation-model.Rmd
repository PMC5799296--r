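---
title: "A compartmental model of TDP-43 autoregulation, fragmentation and aggregation"
author: "tdp43nar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental model of TDP-43 autoregulation, fragmentation and aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

TDP-43 is an essential, aggregation-prone nuclear RNA-binding protein whose
cytoplasmic accumulation and nuclear clearance define the pathology of ALS
and frontotemporal dementia. Cells hold nuclear TDP-43 in a narrow band
through negative autoregulation (NAR): nuclear TDP-43 binds the 3'-UTR of
its own pre-mRNA and diverts transcripts into alternatively spliced isoforms
that are destroyed by nonsense-mediated decay (NMD). Transcription therefore
runs far above what steady-state expression requires — a *transcriptional
redundancy* of roughly 2.7–3.8-fold in adult mouse cerebrum — and the NMD
flux is the dial the cell turns.

`tdp43nar` implements a deterministic compartmental model of this system:
eight pools (canonical endogenous mRNA; nuclear and cytoplasmic protein;
fragmented and aggregated TDP-43; and exogenous mRNA/protein pools for
transgene experiments), mass-action transport and decay, a repressive Hill
law for canonical mRNA production, and a cooperative, fragment-seeded
aggregation flux. The package's centre is `calibrate_tdp43()`, which
reconstructs all rate constants from published steady-state constraints and
returns a fitted model object with the usual methods (`coef`, `residuals`,
`simulate`, `predict`, `plot`).

## Model equations

Writing $m$, $N$, $C$, $F$, $A$ for canonical mRNA, nuclear protein,
cytoplasmic protein, fragments and aggregates (with exogenous counterparts
$m_x$, $N_x$, $C_x$, totals $N_T = N + N_x$, $C_T = C + C_x$):

$$\dot m = k_2\,\mathrm{pre}\,
  \frac{K_{nar}^{n}}{K_{nar}^{n} + N_T^{\,n}} - d_m m$$

$$\dot C = k_{tl} m + k_{exp} N - (k_{imp} + d_c) C -
  \frac{C}{C_T}\left[\phi_{frag} + \phi_{agg}\right], \qquad
  \dot N = k_{imp} C - (k_{exp} + d_n) N$$

$$\phi_{frag} = k_{frag} C_T, \qquad
  \phi_{agg} = k_{agg}\,
  \frac{C_T^{\,n_{agg}}}{aggK^{\,n_{agg}} + C_T^{\,n_{agg}}}
  \left(1 + fe\,\frac{F^{\,n_{seed}}}{F_{1/2}^{\,n_{seed}} +
  F^{\,n_{seed}}}\right)$$

$$\dot F = \phi_{frag} + k_{fa} A + k_{upt} F_{ext} - d_f F, \qquad
  \dot A = \phi_{agg} - (k_{fa} + d_a) A$$

The exogenous pools obey the same transport, translation, degradation and
loss-sharing laws; their mRNA is produced at a constant rate $k_{tc,ex}$
(no autoregulation — the transgene lacks the 3'-UTR) but the exogenous
*protein* represses endogenous production through $N_T$. Loss fluxes shared
by the two cytoplasmic pools are apportioned by pool size, which conserves
total flux and is symmetric.

In the NAR(−) control variant the Hill factor is frozen at its baseline
value $1 - Y$ (0.35 by default), so NAR(+) and NAR(−) share an identical
unperturbed steady state and differ only in their *response* to
perturbations.

### Why the aggregation law has this shape

Two features of the aggregation term are deliberate and load-bearing:

1. **Aggregates fragment** ($k_{fa} A$ feeds the fragment pool). Truncated
   TDP-43 species are produced from aggregated material as well as from
   soluble cytoplasmic protein, and this is what closes the positive
   feedback loop fragments → aggregation → fragments.
2. **Seeding is cooperative** (the enhancement is a Hill function of $F$
   with exponent $n_{seed} = 4$, a nucleation-like law). A *linear*
   fragment enhancement cannot produce two stable states at all: at steady
   state $F$ and $A$ are slaved to $C_T$, $C$ is proportional to $N$
   (nuclear balance), and $m$ is slaved to $N$, so every steady state is a
   root of a single scalar balance — a strictly decreasing production curve
   against a strictly increasing loss curve, hence exactly one root. With
   the cooperative seeding loop the loss curve folds, and the model gains
   the coexisting healthy state (high nuclear TDP-43, trace aggregates) and
   disease state (low nuclear TDP-43, elevated mRNA, high aggregates) that
   the biology demands, together with hysteresis: once the disease state is
   entered it persists when the triggering disturbance is removed.

The vicious cycle runs through autoregulation itself: an aggregation sink
drains cytoplasmic protein, nuclear TDP-43 falls, repression is released,
production rises, and the new protein feeds the aggregates. In the NAR(−)
control the supply is fixed, the sink starves the cytoplasm, the
concentration-dependent aggregation flux quenches itself, and no collapse
occurs — robustness and fragility are two faces of the same loop.

## Calibration

`calibrate_tdp43()` proceeds in three layers.

**Exact algebra.** The baseline is normalised to nuclear protein = canonical
mRNA = 1. Given the NMD flux fraction $Y = 0.65$, the cytoplasmic/nuclear
ratio 0.15 and the degradation-rate ratios ($d_c = 5 d_n$,
$d_n = 0.05 d_m$, $d_f = 3 d_c$, $d_a = 0.2 d_n$), the dependent constants
are solved exactly: $K_{nar} = ((1-Y)/Y)^{1/n}$, $k_2\,\mathrm{pre} =
d_m/(1-Y)$, $k_{imp} = (k_{exp} + d_n)/0.15$, and $k_{tl}$ from the
cytoplasmic flux balance, so the stored baseline is an equilibrium to
machine precision. Nuclear exchange is set fast relative to degradation
($k_{exp} = 20\,d_n$) so the C/N ratio is transport-dominated; only the
ratio is constrained by data.

**Deterministic least squares inside feasibility walls.** The six free
shape constants ($n_{hill}$, $k_{frag}$, $k_{agg}$, $aggK$, $fe$,
$k_{fa}$) are fitted by Nelder–Mead (fixed start, no randomness) to the
four published validation values — heterozygous-knockout steady mRNA 79%
and nuclear protein 82%, transgenic endogenous nuclear protein 39% and
total nuclear protein 138% — with residuals scaled by the ±3-point
acceptance tolerance. Because these four numbers leave the aggregation law
underdetermined, the published *qualitative* behaviours are imposed as
penalty walls, each evaluated by damped-Newton root existence: the model
must be bistable at the calibrated baseline; `agg_K`×0.6 must destroy the
healthy branch (and a disease branch must exist there); the transgenic
healthy branch must survive; the import-collapse threshold must lie inside
the sweep range; doubled transcription must not collapse; and reducing
transcription to 40% must extinguish the disease branch. The default
starting point lies inside this feasible region (it was located by a coarse
design-space scan); the fit then only polishes the quantitative targets.

**Time scale.** All per-time constants are finally rescaled uniformly so
the translation-arrest half-life equals 110 relative time units exactly.
Steady states, ratios and every dimensionless quantity are invariant under
this rescaling, so it cannot disturb the fit.

Fixed structural choices (not fitted): $n_{agg} = 4$, $n_{seed} = 4$,
$F_{1/2} = 0.20$ r.u. The trace bound (baseline fragments and aggregates
< 0.02 r.u.) is enforced as a penalty.

```{r, eval = FALSE}
library(tdp43nar)
model <- calibrate_tdp43() # ~1.5 min, deterministic
model
coef(model)[c("Knar", "n_hill", "k_tl", "agg_K")]
residuals(model)
```

## Numerical machinery

* **Integration**: `deSolve::lsoda` (stiff-capable; the seeding switch
  makes the disease transition stiff), relative tolerance $10^{-10}$,
  piecewise-constant parameters with integrator restarts at perturbation
  switch points, so states are continuous and only derivatives jump.
  Negative excursions from adaptive stepping are clipped at zero and
  counted on the trajectory object.
* **Steady states**: damped Newton with a finite-difference Jacobian and
  projection onto the non-negative orthant; stability from the dominant
  eigenvalue. `settle()` integrates in growing chunks until
  $\max|\dot x| < 10^{-8}(1 + \max|x|)$ — a residual criterion, not
  flatness, because the disease transition has a long quasi-plateau that
  fools flatness tests. Settling and root-finding are cross-checked against
  each other on monostable scenarios (they agree to $<10^{-4}$).
* **Half-life**: dense output plus spline root-bracketing for the first
  crossing of half the initial total soluble protein. Fragments and
  aggregates are excluded from the total; at baseline they are ≤ 2% of it,
  so the choice is numerically immaterial.
* **Hysteresis**: quasi-static continuation (each grid point settled from
  the previous point's state), run down then up; the hysteresis window is
  where the two directions classify differently.
* Everything is deterministic: two identical calls return identical
  objects, and calibrated parameter files serialize byte-identically.

## Scenarios

All of the model experiments are one-call scenarios on the fitted object:
`heterozygous_ko()`, `transgenic()` and `transgenic_dose_response()`,
`parameter_sweep()` (linear factor grid 0.5×–2×, both NAR modes),
`redundancy_stages()` (five NMD fractions Y = 0.20, 0.50, 0.65, 0.75,
0.80, each preserving the baseline steady state exactly by re-solving
$K_{nar}$ and rescaling the pre-mRNA supply by $(1-Y_{base})/(1-Y)$),
`therapy()` (persistent disturbance, transcription reduction at the first
disease classification), `propagation()` (six extracellular fragment
levels with constant uptake flux $k_{upt} F_{ext}$ from an inexhaustible
exterior reservoir), `bistability_scan()` and `tradeoff_summary()`.

The healthy/disease classifier is deliberately simple and always reports
its thresholds: disease iff total nuclear TDP-43 falls strictly below half
its baseline *and* fragments or aggregates strictly exceed 0.1 r.u. The
figure evidence shows two shaded regimes with no printed cutoffs, so these
thresholds are this package's own choice; they are arguments everywhere
they are used.

The propagation uptake coefficient defaults to $d_f F_{1/2}/20$, chosen
once so that the default six-level grid brackets the untreated disease
threshold (≈1.6 r.u.) and the threshold under halved transcription
(≈3 r.u.) — the published description fixes only that "a certain amount"
of extracellular fragmented protein enters the cell.

## What the calibrated model reproduces — and where it deviates

A single calibrated set reproduces jointly: knockout mRNA/protein
79.3%/80.1% (published 79/82), transgenic endogenous/total nuclear protein
39.5%/136.3% (published 39/138), half-life 110 r.t.u. (exact by
construction), NMD flux 65% and C/N 0.15 (exact), the
NAR(+)-robust/NAR(−)-fragile transcription sweep (nuclear deviation 0.20
vs 0.57 over 0.5×–2×), an import-collapse threshold at ≈0.64× (published
"approximately three-quarters"; only below, never above), agg_K-driven
bistability with a hysteresis window reaching factor 1.0 (the disease
state persists after the disturbance is removed), the staged
robustness/fragility split for seven of eight swept factors, and the
propagation threshold shift under halved transcription.

Two published behaviours are *not* reproduced at their stated strength,
and both trace to the single cooperative seeding knee:

1. **Therapy mRNA level.** Reducing transcription to 40% after disease
   onset does return the system to the healthy state, but the rescued
   mRNA settles at ≈0.74 of baseline rather than "nearly normal". At the
   stable rescued state fragments clear, the aggregation tax vanishes,
   protein tracks mRNA, and the mRNA is pinned at the value the Hill
   compensation allows, $m = (0.4/0.35) H(m) \approx 0.74$ for the Hill
   coefficient (≈3.8) that the knockout values require. A nearby root with
   mRNA ≈ 0.97 exists but is locally unstable.
2. **Fragment-degradation fragility.** Halving $d_f$ doubles the fragment
   level (0.01 → 0.025 r.u.) but does not reach the seeding knee at any
   redundancy stage, so this factor types as robustness rather than
   fragility. Moving the knee low enough to change that would keep the
   disease state alive under the 40%-transcription therapy.

Both deviations are structural consequences of this package's aggregation
law, which the source description leaves open; they are documented here
rather than hidden behind looser tests.

## What the model does not attempt

No stochasticity, spatial structure, stress-granule physics, downstream
splicing targets, multi-cell propagation topologies, or combined
multi-factor disturbances. Time and amounts are relative units; the only
anchor to physical time is the measured half-life range (4 to >34 h), via
`time_unit_conversion()` — 100 r.t.u. correspond to roughly 3.6–31 h.
Passing the validation suite shows the network reproduces the published
steady-state pattern and regime structure under these laws; it does not
validate the laws against time-resolved measurements, which the relative
units make impossible by construction.

## Problem sizes used in the test suite

Calibration solves two scenario steady states per objective evaluation
(few hundred evaluations, ≈1.5 min); sweeps use the published 100-step
grids; hysteresis continuation uses 25 points per direction; the staged
trade-off analysis settles 5 stages × 8 factors × 2 directions. The entire
suite, including one full calibration, runs in a few minutes on one CPU.
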
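---
title: "Methods: an ocular TMDD disease model for anti-TNF-α antibodies in anterior uveitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an ocular TMDD disease model for anti-TNF-alpha antibodies in anterior uveitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocutmdd)
```

## The problem

Anterior uveitis (iritis) is driven in large part by elevated tumour necrosis
factor α (TNF-α) in the anterior segment of the eye. Systemic anti-TNF-α
monoclonal antibodies control it at the cost of an intensive regimen — a
loading dose followed by maintenance injections every other week — while
blood–ocular barriers keep most of the circulating antibody out of the
aqueous humour. An intravitreal sustained-release device placed in the
vitreous inverts that geometry: a small zero-order release directly into the
eye can hold the anterior chamber at therapeutic drug levels for six months
per injection.

`ocutmdd` simulates this trade-off in a uveitis-diseased rat: free TNF-α
kinetics in the anterior chamber (aqueous humour, AH) and the iris–ciliary
body (ICB, plasma and interstitial fluid — the biophase), under intravenous
(IV) multiple dosing or intravitreal (IVT) zero-order devices, and uses the
model to choose the IV reference dose, optimize the device release rate
against a 90 % TNF-α-reduction objective, and map device-emptying failure
modes.

## Model structure

Five well-stirred compartments carry free drug: venous plasma, ICB plasma,
ICB interstitial fluid, aqueous humour and vitreous. TNF-α is treated as a
stationary molecule — synthesised and degraded locally, never transported —
and exists, together with the drug–TNF-α complex, in the first four
compartments; the vitreous is a drug depot only.

**Turnover.** In each TNF-α-bearing compartment,

$$\frac{dA_{TNF}}{dt} = SF \cdot k_{deg} \cdot A_{TNF}^{healthy} - k_{deg} \cdot A_{TNF}(t) ,$$

so the healthy steady state is the 1 pM baseline and, under systemic
inflammation (synthesis factor $SF = 7$), the untreated system relaxes to the
7 pM pathological plateau with rate $k_{deg} = 0.223\,h^{-1}$
($t_{1/2} \approx 3.1$ h).

**Binding.** Full (non-approximated) 1:1 target-mediated drug disposition in
every TNF-α compartment of volume $V$:

$$\frac{dA_{cx}}{dt} = \frac{k_{off}}{K_d} A_{TNF} \frac{A_{drug}}{V}
  - k_{off} A_{cx} - k_{deg,cx} A_{cx} .$$

Binding consumes one unit each of free drug and free TNF-α; dissociation
returns both; complex degradation ($k_{deg,cx} = 0.18\,h^{-1}$) removes both
partners. Whether complex catabolism regenerates free target is not
observable from the endpoints used here; we chose the single-sink form.
Association rates are derived as $k_{on} = k_{off}/K_d$; the shipped constants
are published values for adalimumab ($K_d$ 127 pM, $k_{off}$ 0.576 h⁻¹),
golimumab (18 pM, 0.335 h⁻¹) and infliximab (44 pM, 0.720 h⁻¹), all with
MW ≈ 144–147 kDa.

**Disease-state recovery.** Five ocular processes are altered by
inflammation and recover linearly with the *local* complex fraction
$f = A_{cx}/(A_{TNF}+A_{cx})$ (defined as 0 when no TNF-α is present),
each read at the anatomical location where the process physically occurs:

| process | meaning | coupling location |
|---|---|---|
| $Q_{AH}$ | aqueous humour drainage | AH |
| $f_{Schlemm}$ | fraction of drainage via Schlemm's canal (to blood) | AH |
| $Q_{AV}$, $Q_{VA}$ | anterior↔posterior bulk flows | ICB interstitial |
| $\sigma_{AH}$ | reflection coefficient at the ICB vascular/aqueous barrier | ICB plasma |

$$x(t) = x^{disease} + (x^{healthy} - x^{disease}) \cdot f(t) .$$

With zero complexation the eye sits at its diseased physiology (ocular
hypotony, reduced bulk flows, leaky blood–aqueous barrier); complete
complexation restores the healthy values.

**Drug transport.** Vitreous→AH at $Q_{VA}(t)$ and AH→vitreous at
$Q_{AV}(t)$; aqueous secretion from ICB plasma at
$Q_{AH}(t)(1-\sigma_{AH}(t))$; AH drainage $Q_{AH}(t)$ split
$f_{Schlemm}(t)$ to venous blood and the rest uveosclerally into the ICB
interstitium; venous↔ICB-plasma perfusion $Q_{ICB}$; diffusive
plasma↔interstitial exchange $PS_{ICB}$; interstitial lymph $L_{ICB}$ to
venous plasma; and a lumped first-order systemic clearance $CL_{sys}$. FcRn
recycling and endosomal kinetics are deliberately not modelled — whole-body
antibody disposition is collapsed into $CL_{sys}$, which is the right level
of detail for ranking ocular regimens but not for predicting absolute plasma
kinetics.

**Dosing.** IV boluses are instantaneous additions to venous plasma. An IVT
device releases at a strict zero-order rate into the vitreous until its
finite load ($rate \times duration$) is exhausted — a hard stop, which is an
idealisation of reservoir-type implants. A premature-emptying variant
releases the same load at `load/(duration - weeks_early)` and stops early.
Each IVT injection also triggers a transient intraocular-pressure
perturbation multiplying $Q_{VA}$ and $Q_{AH}$ by
$1 + a\,e^{-t/\tau}$ (defaults $a = 0.2$, $\tau = 24$ h, switchable off);
the amplitude and time constant are plausible-scale choices, not fitted
values, and none of the steady-state endpoints is sensitive to them.

**Timeline.** Simulations start one week before disease induction at the
healthy steady state (a built-in flatness check); at $t = 0$ the synthesis
factor switches to 7 and the recovery couplings activate, so the untreated
eye reaches the pathological plateau within a day and treatment begins at
week 1.

## Calibrated physiology

The drug/target/complex constants above are published values. The
ocular/systemic physiology is **calibrated, not measured** — the values
shipped in `default_physiology()` (and
`inst/extdata/default_physiology.yaml`) were fixed once, before any
acceptance checks were run, as follows:

* Volumes (AH 25 µL, vitreous 54 µL, ICB plasma 2 µL, ICB interstitium
  10 µL, venous plasma 10 mL) and the healthy aqueous turnover
  $Q_{AH} = 26$ µL/h are typical rat ocular physiology.
* $\sigma_{AH}^{healthy} = 0.93$ sets the IV steady-state AH:plasma drug
  ratio to $1-\sigma \approx 0.07$, which, combined with
  $PS_{ICB}/L_{ICB} = 24$, gives the ~14-fold ICB-interstitial:AH exposure
  gradient characteristic of systemic antibody dosing against the
  blood–aqueous barrier.
* $CL_{sys} = 0.027$ mL/h (plasma half-life ≈ 11 days) reproduces
  plasma-exposure magnitudes of tens of nM for ~25 µg IV doses.
* Disease reductions $a = 2$, $b = c = 3$ on $Q_{AH}$, $Q_{AV}$, $Q_{VA}$,
  with $f_{Schlemm}: 0.93 \to 0.70$ and $\sigma_{AH}: 0.93 \to 0.60$,
  encode hypotony, flow reduction and barrier breakdown.

Because the upstream whole-body parameterisation behind this disease system
is not public, *absolute* concentrations are not reproducible from published
constants alone; the package's contract is therefore qualitative and
structural — gradients, rankings, monotonicities and the failure-mode
ladder — plus the exact arithmetic layer (unit bridges, emptying rates, fold
changes, dose totals). Under the shipped calibration the optimal release
rates come out at 1.05 (adalimumab), 0.36 (infliximab) and 0.20 µg/week
(golimumab): the expected ranking (slowest binder needs the fastest release),
at somewhat lower absolute levels than the published design values, and the
IV reference dose for adalimumab lands at ~37 µg.

## Numerical choices

* Stiff-capable LSODA integration, `rtol = 1e-8`, `atol = 1e-10` pmol
  (configurable). The right-hand side exists twice — a readable R reference
  and the compiled C version used by default — and the test suite holds
  their trajectories together to ≤ 1e-5 scaled difference.
* Integration restarts at every bolus, device start, device exhaustion and
  at induction, so no discontinuity falls inside a solver step; exhaustion
  times are computed exactly as `start + load/rate`.
* Output grid: hourly for the first week after each event, 6-hourly
  elsewhere (TNF-α's 3 h half-life sets the resolution requirement near
  events). Steady-state averages are trapezoidal, over the last complete
  dosing interval (weeks 50–52 for the IV default, 25–49 for the IVT
  default) — the averaging window is a convention, stated rather than
  inferable.
* The complex fraction at zero total TNF-α is defined as 0 (disease value),
  avoiding 0/0.
* The reduction endpoint is reported with the positive-magnitude convention
  $(1 - C_{avg}/(SF \cdot C^{healthy})) \cdot 100$.
* Dose/rate design uses bisection (≤ 12 iterations, relative tolerance
  1e-3) justified by monotonicity of the reduction in dose/rate, which the
  tests verify against a dense grid scan.
* The outcome classifier treats "pathological" with a 1 % tolerance band
  because the 7 pM plateau is approached asymptotically; the
  first-above-objective location is the highest concentration, ties broken
  AH → ICB interstitial → ICB plasma → venous (the anterior chamber is the
  sentinel compartment).
* In the sensitivity sweep, synthesis-factor multipliers that would push
  $SF$ below 1 are invalid under the disease definition and are reported as
  `NA` cells rather than simulated.

## Synthetic data and what passing tests mean

The generator (`sample_physiology()`, `noisy_observations()`) emulates
deterministic model output with multiplicative lognormal observation error
(the standard PK observation model) and median-preserving lognormal
parameter jitter; fractions are jittered on the logit scale. It does **not**
emulate inter-animal variability structure, assay limits of quantification,
flares/tolerance, or model misspecification — so parameter-recovery results
(`recover_parameters()`) demonstrate estimator consistency and practical
identifiability of the documented subsets ({SF}, {SF, CL_sys},
{release rate}) under the model's own error assumptions, not performance on
real ocular data.

Problem sizes used throughout the tests and the acceptance script: 52-week
horizons with 26 IV or 2 IVT events for design computations, 2–8-week
horizons for recovery studies (20 observations, CV 0.2, 20 replicates), and
0.1-resolution grid scans as the optimizer oracle.

## Known limitations

* Constant disease burden: $SF$ is time-invariant; flares, tolerance and
  anti-drug antibodies are out of scope.
* The lumped $CL_{sys}$ makes systemic washout mono-exponential and, under
  the shipped calibration, somewhat slow; after device exhaustion the
  venous compartment therefore re-escalates last, and the full relapse to
  pathological levels in *all* compartments requires longer emptying
  advances than the anterior chamber alone would suggest.
* No binding in the vitreous (no TNF-α pool there) — anterior structures
  are where the disease readouts live.
* Deterministic only: no population variability; `sample_physiology()`
  provides scenario spread, not a statistical model of a rat population.
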
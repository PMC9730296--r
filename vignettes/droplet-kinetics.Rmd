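---
title: "Droplet-on-demand absorbance kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet-on-demand absorbance kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropkin)
```

`dropkin` models a tubing-based droplet-on-demand platform for steady-state
enzyme kinetics: a syringe pump aspirates an enzyme solution from a stirred
microtiter well while substrate is injected into that well, so the resulting
train of ~60 water-in-oil plugs carries a monotone substrate gradient - one
droplet, one concentration. The train is read by a line camera at up to 12
detection points, and the flow direction is reversed repeatedly so every
droplet is re-read at several time points. The package contains both a
physics-based simulator of this instrument and the analysis pipeline that
turns a raw transmitted-light trace back into Michaelis-Menten parameters.
This vignette records the models, the tunable parameters, and the design
decisions behind both halves.

## The forward model

### Well gradient (CSTR mass balance)

During gradient formation the well is treated as an ideally mixed
continuously stirred tank with time-varying volume:

$$\frac{dV}{dt} = Q_{inj} - Q_{draw}, \qquad
  \frac{d(VS)}{dt} = Q_{inj}\,C_{stock} - Q_{draw}\,S, \qquad
  \frac{d(VE)}{dt} = -Q_{draw}\,E.$$

Defaults follow the instrument's operating point: a 40 uL enzyme well, 5 uL
of substrate stock injected at 10 uL/min, withdrawal at 4 uL/min, for 30 s.
Mixing is taken as instantaneous - the well is stirred at 1500 rpm, so the
gradient is set by the fluidics alone and no mixing-lag term is modelled.
Note that withdrawal removes volume and solute together, so it leaves
*concentrations* untouched: enzyme dilution comes only from the injected
volume, which bounds E(last)/E(first) below by 40/45. `simulate_well()`
integrates the balance with `deSolve::lsoda` (rtol 1e-10) and carries a
cumulative-withdrawal state so that the substrate ledger (injected = in well
+ withdrawn) closes to solver tolerance. The linear system also has a closed
form, which the test suite uses as an independent oracle together with a
fixed-step RK4 integrator.

### Droplet train

Droplets detach at a fixed period $(V_{drop} + V_{spacer})/Q_{draw}$.
Droplet volume is ~30 nL; the oil spacer volume is not published, and 3 nL
was chosen once so that the default 30 s gradient yields exactly 60 droplets,
the train size the instrument produces. Droplet $i$ (0-based) carries the
well composition at the midpoint of its aspiration window,
$t_i = (i + 0.5)\,T$; the same midpoint serves as the reaction time origin,
since the droplet contents start reacting at mixing in the well, not at their
first optical read.

### In-droplet reaction

Each droplet is a closed batch reactor: $dS/dt = -k_{cat} E_0 S/(K_M + S)$,
with $P = S_0 - S$. `progress_curve()` integrates this ODE rather than
extrapolating a straight line, so the analysis pipeline's initial-rate
assumptions are themselves testable against the simulator. The implicit
integrated form $K_M \ln(S_0/S) + (S_0 - S) = k_{cat} E_0 t$ is used only by
the tests (root-solve oracle) and, through its Lambert-W solution, by the
analysis-side progress fit.

### Optics

Each droplet transit produces a rectangular trough in transmitted light of
duration $V_{drop}/Q_{draw}$ (0.45 s, i.e. 90 samples at the 200 Hz
acquisition rate). Trough depth obeys the Beer-Lambert law
$I = g_c I_0\,10^{-(A_{plug} + \varepsilon \ell P)}$ with per-channel gains
$g_c$ spanning at most the ~30% illumination deviation observed across
detection points (default: a linear ramp 1 to 0.7). The product
concentration is evaluated at the trough-center time and held constant over
the 0.45 s transit. Gaussian intensity noise (sd `noise_sd` x baseline,
default 0.1%) is added per sample.

`droplet_contrast` (default 0.12 absorbance units) is the residual
transmission contrast between an aqueous plug and the carrier oil. Without
it a product-free droplet would be optically invisible and the low-substrate
end of the gradient could never be detected or indexed; with it, every plug
dims the channel by >20% while even a full-absorbance trough leaves the
detection threshold (20% of the channel's dynamic range) below that
contrast, so detection is uniform across the gradient. The default
absorptivity-pathlength product (16000 1/(M cm) x 0.02 cm = 320 /M at
405 nm) describes partially ionized para-nitrophenol in the 0.2 mm tubing;
the analysis never consumes either number directly because calibration
cancels them.

Edge artifacts from refractive-index mismatch are off by default (the
carrier oil is index-matched); an optional `edge_artifact` spike term and a
pre-gradient junk-segment injector exist for segmentation stress tests. The
~5 priming air bubbles of a real run are not simulated.

### Pass schedule

The published runs alternate pull and push over 30 min with six reads of the
gradient, but the per-pass timing is not printed. The default schedule
therefore spaces passes uniformly: first arrival 60 s after the start of
gradient generation, 280 s between passes, 10 s of travel between adjacent
detection points, channel order reversing with direction. The calibration
train - 15 droplets of 1 mM product generated after the gradient - sits at
the generator-side end of the tubing, so it is rendered on the final push
pass, leading the gradient train by a 10 s oil gap. All of these are
configurable; arrival times may also be supplied as an explicit matrix.

## The analysis pipeline

### Boundary detection

Droplets are found on a centered moving average of the intensity: a droplet
is a maximal run where the smoothed signal drops below
`baseline - threshold_frac x (baseline - min)`, with the baseline a rolling
median over droplet-free spans. The moving-average window must be shorter
than the inter-droplet oil gap - 45 ms (9 samples) at the default geometry -
or adjacent troughs merge; the default is 7 samples (35 ms), long enough to
suppress single-sample noise. Boundaries are refined on the raw signal at
the half-depth crossing, and the absorbance is
$\log_{10}(I_{baseline}/\bar I)$ with $\bar I$ averaged over the central 50%
of the trough, avoiding edge transients. An AUC mode (absorbance averaged
across the whole trough) exists for fidelity with acquisition software that
integrates between fixed positions; on rectangular troughs the two agree. A
trace is declared droplet-free unless its dynamic range exceeds 10x the
smoothed noise floor, which keeps pure-noise traces at zero detections.

### Segmentation, anchoring, matching

Detections cluster into passes wherever the time gap exceeds 5x the median
inter-droplet gap; with too few droplets per train for gap statistics, the
scheduled arrival windows are used instead. Extra clusters beyond the
scheduled pass count are set aside, the temporally last one being the
calibration train. The generation-order end of each train is anchored
automatically - the temporal end on pull passes, the temporal start on push
passes - with a manual override mirroring interactive end-time marking.
Every detection then receives a generation index from its offset to the
anchor in units of the train's own median droplet period, which tolerates
isolated missing droplets; detections more than 30% of a period off the
grid are dropped with a log record. Two flow reversals compose to the
identity on the index, which the simulator round-trip tests verify exactly.

### Calibration and the blank

Because the detector response is linear well beyond 1 mM product, a
single-level zero-intercept calibration suffices:
slope = (mean A_calib - A_blank)/c_calib per channel. The blank is the
absorbance of a product-free plug (the plug/oil contrast). It is estimated
from the earliest pass by fitting the droplet-index profile
$A(i) = \mathrm{offset} + \mathrm{amplitude}(1 - e^{-\kappa i})$ and
extrapolating to $i = -0.5$, the index at which the well still held no
substrate - using the offset at $i = 0$ instead would absorb the first
droplet's own product and visibly bias fast reactions. The limit of
detection is $3.29\,\sigma_{blank}/\mathrm{slope}$ from the per-sample
baseline absorbance scatter; 3.29 is the two-sided 95% convention
($\alpha = \beta = 0.05$), and the multiplier is configurable since the
instrument's published "95% confidence" does not pin the convention down.
At the default 0.1% intensity noise this lands in the low-micromolar range,
the same order as the instrument's 5-18 uM.

The same profile fit doubles as an outlier screen: droplets more than 4x
the profile RMS off the curve in a majority of passes are excluded from the
kinetic fit but retained, flagged, in all outputs. The profile is never used
to assign concentrations.

### Concentration assignment

Substrate and enzyme concentrations are assigned drop-by-drop from the
fluidic parameters alone: the analysis re-solves the same well balance and
evaluates it at $(i + 0.5)\,T$. When analysis and simulator share a fluidic
configuration this is an exact inverse, which is tested; on a real
instrument its accuracy is set by pump calibration, a term outside this
model.

### Initial rates

The default estimator is the instrument's: ordinary least squares of
absorbance on read time, $v_0 = \mathrm{slope}/(dA/dc)$, with standard error
and $r^2$ from the regression. That is exact while consumption over the read
window is small, and droplets whose observed conversion exceeds 10% of their
assigned substrate are flagged. For those droplets a linear fit is known to
underestimate $v_0$ - in the fastest published regime (kcat 23 1/s, 5 nM
enzyme, KM 13.7 uM) every droplet is more than half converted before it
first reaches a detection point, and no linear fit over any subset of reads
can recover the rate. The estimator therefore switches, data-driven, to an
integrated Michaelis-Menten progress fit of that droplet alone: product vs
reaction time with the assigned $S_0$ fixed and three free parameters (the
initial rate $v_0$, an apparent Michaelis constant, and a baseline offset
that absorbs residual blank error). It is parameterized directly in $v_0$
(the t = 0 slope), on a log scale, solved by Levenberg-Marquardt on the
Lambert-W closed form; the apparent K may run to its bound in the
first-order regime without destabilizing $v_0$, and a single-exponential
progress fit is the fallback. One identifiability limit remains: a droplet
whose fitted curve is already >90% converted at its first read constrains
$v_0$ only from below (any faster rate fits equally well), so such droplets
are flagged `unresolved_fast` and excluded from the Michaelis-Menten fit,
retained in the outputs. Whether published analyses used all six reads
or dropped late reads for fast reactions is not stated; this package keeps
all reads and records the method used per droplet.

Rates below the LOD-derived resolution (LOD divided by the read-time span)
are reported with a `below_resolution` flag rather than suppressed.

### Michaelis-Menten fit and aggregation

Each detection point yields one dataset of (S, E, v0) triples, sorted by S,
gated on >= 8 usable droplets spanning a > 4-fold substrate range.
`fit_mm()` runs unweighted nonlinear least squares of
$v_0 = k_{cat} E_i S_i/(K_M + S_i)$ with each droplet's own $E_i$ - the
enzyme dilutes ~11% along the gradient, so a single E would bias kcat.
Starts are $k_{cat,0} = \max v_0/\min E$ and $K_{M,0}$ = S at half-maximal
$v_0/E$; standard errors come from the Jacobian at the optimum;
non-convergence is reported, never clamped. A 1/se^2-weighted mode exists
but is not the default, matching the published unweighted treatment.
Detection points are aggregated as plain replicates (mean, n-1 sd, RSD per
substrate); no hierarchical model is attempted.

## What the simulator does and does not emulate

The generator reproduces: the stirred-well gradient and enzyme dilution, the
~60-droplet train, Beer-Lambert troughs with per-channel gains and plug
contrast, pass reversals with order inversion, the late calibration train,
and white intensity noise. It does not reproduce: droplet volume dispersion,
shrinkage or coalescence, interdroplet product transport (not observed on
the instrument, with its index-matched oil and low surfactant), pump pulsing
or flow-rate error, baseline drift, pH-dependent absorptivity shifts, or
enzyme inactivation. Passing recovery tests therefore demonstrates that the
analysis inverts the stated physics faithfully - not that it is immune to
instrument pathologies outside that physics. The conditions of the recovery
tests (concentrations, kinetic truths) are the published assay conditions of
the SN243 glycosidase panel, bundled as `glycosidase_panel()`.

## Numerical choices and problem sizes

- ODE integration: `lsoda`, rtol 1e-10/1e-11, absolute tolerances scaled to
  the state; progress curves are clamped to $[0, S_0]$ against roundoff.
- Lambert W: Newton on the convex form $e^x + x = y$ in $x = \ln w$, safe
  for arguments up to the zero-order regime's $e^{S_0/K}$ scale.
- Degenerate inputs: zero-length gradients yield empty droplet sets; a
  kcat = 0 truth renders flat (contrast-only) troughs; all-zero rate sets
  return `converged = FALSE`; all-flagged datasets are marked unfit and
  skipped, never fatal.
- Tie-breaks: the pass-count mode takes the smallest count on ties; the
  calibration train is the temporally last extra cluster.
- Test problem sizes: unit tests use a compact 3-pass, 7-minute, 1-2 channel
  geometry with the full droplet geometry retained; the acceptance-grade
  recovery runs use the full 6-pass, 30-minute schedule on 4 detection
  points (4.3 M samples for 12 channels, ~1.4 M for 4) and finish in about a
  minute per substrate on one core.

## Known limitations

- The fluidic inverse trusts the configured rates and volumes; no
  self-calibration of the gradient from the trace is attempted (the
  exponential profile fit is diagnostic only).
- KM values near or below the LOD-derived concentration resolution (around
  1 uM for pNP) are reported but cannot be accurate, mirroring the physical
  instrument's optical limit.
- The per-droplet progress fit assumes the batch MM rate law within a
  droplet; substrate inhibition or cooperativity would bias it. Alternative
  rate-law variants are deliberately out of the default path.
- Pass timing is uniform by default; real tubing travel times vary with
  back-pressure, which only matters if it moves read times by a large
  fraction of a pass interval.
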
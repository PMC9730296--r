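# dropkin

Simulation and analysis of multiplexed **droplet-on-demand absorbance
kinetics**: steady-state enzyme kinetics measured in a train of ~60
nanoliter water-in-oil droplets that carry a substrate concentration
gradient, read repeatedly at up to 12 detection points of a line camera by
reversing the flow direction between reads.

The package is for two audiences: enzymologists who want to prototype or
sanity-check analysis settings for such an instrument against a ground-truth
simulator, and developers of the analysis itself, who need every step — from
raw transmitted-light trace to Michaelis–Menten parameters — exposed,
testable, and invertible against known physics.

## The model

One droplet is one reaction at one substrate concentration. The well the
droplets are drawn from behaves as a stirred tank with simultaneous
injection and withdrawal:

    dV/dt = Q_inj − Q_draw
    d(V·S)/dt = Q_inj·C_stock − Q_draw·S
    d(V·E)/dt = −Q_draw·E

so droplet *i*, aspirated at t = (i + ½)·T, carries known (S₀, E₀). Inside a
droplet the reaction follows dS/dt = −k_cat·E₀·S/(K_M + S); optically, each
droplet transit is a Beer–Lambert trough, I = g·I₀·10^−(A_plug + ε·l·P).
The analysis pipeline detects troughs on a moving average, segments passes,
tracks each droplet across flow reversals by its anchored position in the
train, calibrates absorbance against a 1 mM product train, assigns (S, E)
from the fluidics, extracts initial rates v₀ (linear fit, switching to an
integrated progress fit for heavily converted droplets), and fits

    v₀ = k_cat · E_i · S_i / (K_M + S_i)

per detection point, aggregating detection points as replicates. See the
methods vignette (`vignettes/droplet-kinetics.Rmd`) for the full account.

## Worked example

Simulate the published assay of the glycosidase SN243 on pNP-β-xylopyranoside
(400 mM stock injected into 1 µM enzyme; plate-reader truth k_cat = 0.4 s⁻¹,
K_M = 23.0 mM) on four detection points, then analyze the trace without
access to the truth:

```r
library(dropkin)
cfg <- panel_run_config("pNP-b-Xyl", n_channels = 4, source = "plate", seed = 1)
sim <- simulate_run(cfg)
ana <- analyze_trace(sim$trace, cfg)
ana$summary
#>       group n_fits mean_kcat      sd_kcat     rsd_kcat    mean_KM        sd_KM
#> 1 pNP-b-Xyl      4 0.4017221 0.0001456375 0.0003625329 0.02333653 2.242558e-05
#>         rsd_KM kcat_over_KM
#> 1 0.0009609648      17.2143
```

The four detection points recover k_cat = 0.4017 ± 0.0001 s⁻¹ and
K_M = 23.34 ± 0.02 mM — within ~1.5 % of the generating parameters, with a
replicate spread far tighter than the physical instrument's (whose RSDs
include pump and optics drift the simulator does not model). Per-channel
detail lives in `ana$fit_table`; per-droplet rates, flags and the
calibration (slope ≈ 320 /M, LOD ≈ 4 µM) in `ana$channels$ch01`.

The same loop runs from the shell via the thin CLI:

```sh
Rscript inst/cli/dropkin simulate --config run.yaml --out sim/
Rscript inst/cli/dropkin analyze  --config run.yaml --trace sim/trace.csv --out results/
Rscript inst/cli/dropkin report   --results results/
```

with `run.yaml` written by `write_run_config()`. Raw traces are CSV
(`time_s`, `ch01`…`ch12` at 200 Hz); the simulator also writes a
ground-truth JSON sidecar that the analysis never reads.

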
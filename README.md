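# hrrflux

Analysis of high-resolution respirometry (HRR) experiments on intact and
permeabilized cells: from raw chamber oxygen traces and
substrate–uncoupler–inhibitor titration (SUIT) event logs to state-resolved
oxygen fluxes and the ratio panel used in mitochondrial bioenergetics. It is
aimed at labs running oxygraph (e.g. Oroboros O2k-style) experiments who
want a scripted, reproducible alternative to manual mark placement — and at
method developers, who get a seeded chamber simulator with known ground
truth for every stage.

## What it computes

Given a trace $C(t)$ (µM O₂) and a titration log, the pipeline

1. differentiates the trace per inter-event segment (sliding local linear
   regression or Savitzky–Golay): $J_V = -\,dC/dt \times 1000$
   pmol O₂ s⁻¹ mL⁻¹, respiration positive;
2. subtracts the calibrated instrumental background $a + bC$ and normalizes
   per million cells: $J = (J_V - a - bC)\,V/N$;
3. segments the run into the protocol's respiratory states (ROUTINE, LEAK,
   OXPHOS, ETS, …), places a steady-state mark on the minimum-variance
   plateau window of each state (ETS = maximum plateau across the CCCP
   titration steps), and subtracts residual oxygen consumption (ROX);
4. derives per-run metrics — flux control ratios $J_s/J_{ETS}$, ATP-coupled
   (net) FCRs $(J_s - J_{LEAK})/J_{ETS}$, coupling efficiencies
   $1 - J_{LEAK}/J_s$, respiratory reserve
   $(J_{OXPHOS}-J_{ROUTINE})/J_{ETS}$, the complex II share of ETS
   capacity, and substrate control factors from paired rotenone-first runs;
5. compares groups (mean ± sd, percent change, unpaired t-test, stars).

Two SUIT protocols are built in: the full titration (`SUIT_MAIN`) and a
rotenone-first complex II protocol with malonate counter-proof
(`SUIT_CII`). User-defined protocols are plain YAML.

The `simulate_*` functions integrate the chamber oxygen balance
$dC/dt = -(\rho\,j(t) + a + bC)/1000$ with exponential plateau transitions
and Gaussian sensor noise, with control and MPP⁺-treated presets whose
ratio structure mirrors published measurements on differentiated
neuroblastoma cells (LEAK/ETS 0.19 vs 0.31, OXPHOS coupling 78% vs 65%,
ETS capacity −62.7%, SCF 0.49 vs 0.52, …).

## Worked example

Five simulated replicates per condition, analyzed and compared:

```r
library(hrrflux)

ctl   <- analyze_runs(simulate_cohort("control", 5, seed = 11))
trt   <- analyze_runs(simulate_cohort("mpp_treated", 5, seed = 12))
cii_c <- analyze_runs(simulate_cohort("control", 5, seed = 11,
                                      protocol_name = "SUIT_CII"))
cii_t <- analyze_runs(simulate_cohort("mpp_treated", 5, seed = 12,
                                      protocol_name = "SUIT_CII"))

cmp <- compare_cohorts(ctl, trt, cii_control = cii_c, cii_treated = cii_t)
format_comparison(cmp[cmp$metric %in% c("fcr", "coupling_efficiency", "scf"), ])
```

```
fcr                          ROUTINE       0.540 ±  0.048 (n=5) vs    0.466 ±  0.044 (n=5)    -13.8%  p=0.03307 *
fcr                          LEAK          0.221 ±  0.044 (n=5) vs    0.379 ±  0.059 (n=5)    +71.3%  p=0.001425 **
fcr                          OXPHOS        0.824 ±  0.034 (n=5) vs    0.866 ±  0.077 (n=5)     +5.2%  p=0.2868 ns
fcr                          ETS           1.000 ±  0.000 (n=5) vs    1.000 ±  0.000 (n=5)     +0.0%  p=1 ns
coupling_efficiency (%)      ROUTINE      59.048 ±  7.319 (n=5) vs   18.830 ±  8.471 (n=5)    -68.1%  p=4.239e-05 ***
coupling_efficiency (%)      OXPHOS       73.178 ±  5.097 (n=5) vs   56.152 ±  6.983 (n=5)    -23.3%  p=0.002275 **
coupling_efficiency (%)      ETS          77.881 ±  4.447 (n=5) vs   62.102 ±  5.929 (n=5)    -20.3%  p=0.001425 **
scf                          OXPHOS_CII    0.521 ±  0.033 (n=5) vs    0.565 ±  0.123 (n=5)     +8.3%  p=0.4682 ns
```

Read: the treated group's dissipative LEAK ratio rises (+71% here; the
ratio of the underlying preset truths is +63%) while coupling falls in
every state — the signature of inner-membrane damage on top of complex I
inhibition — and the complex II substrate control factor is unchanged
within noise, as expected when complex II itself is not a toxin target.
At n = 5 with realistic sensor noise the per-run estimates scatter; the
methods vignette (`vignettes/hrr-pipeline.Rmd`) quantifies the estimator's
detection limits.

A command-line front-end wraps the same functions:

```sh
exec/hrrflux simulate --preset control --n-runs 5 --seed 11 --out-dir runs/ctl
exec/hrrflux analyze  --runs runs/ctl/control_01,runs/ctl/control_02 --out-dir out/ctl
exec/hrrflux compare  --control out/ctl/state_fluxes.csv --treated out/trt/state_fluxes.csv --out-dir out/cmp
```

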
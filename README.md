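# apratedep

Rate-dependent action potential prolongation by potassium channel modulation
in a simulated human ventricular epicardial myocyte.

## The problem

Class III antiarrhythmic drugs prolong the ventricular action potential
duration (APD) to suppress reentry, but blocking a single potassium channel
prolongs APD more at slow rates than at the fast rates of ventricular
tachycardia (*reverse rate dependence*), which undermines their efficacy and
adds pro-arrhythmic risk at slow rates. This package is for cardiac
electrophysiology modelers who want to reproduce and extend the
computational finding that *combinations* — enhancing IKs while blocking IKr
and IK1 — can invert this: same APD prolongation at slow rate, much larger
prolongation at fast rate (*positive rate dependence*), at the price of a
reduced repolarization reserve that can be limited by capping IK1 block.

At its core:

* the ten Tusscher–Noble–Noble–Panfilov (2004) epicardial ionic model
  (CellML parameterization) with scalable maximal conductances
  `sKs·G_Ks`, `sKr·G_Kr`, `sK1·G_K1`, integrated by Rush–Larsen/forward
  Euler at fixed dt = 0.02 ms behind a model-plugin interface (the 2006
  revision ships as a second plugin);
* pacing protocols: threshold search (1-ms pulse, bisection), steady-state
  pacing at a basic cycle length (BCL) for 16 simulated minutes at 1.5×
  threshold, restitution over BCLs, and repolarization-reserve estimation by
  a constant −0.1 pA/pF depolarizing injection during the AP;
* AP shape features: amplitude (APA), APD90, phase 1/2/3 boundaries from
  current-based landmarks (total-current sign change; IK1 reaching 10% of
  its repolarization peak), phase-average ionic currents via the single-cell
  slope identity `Īion/Cm = −ΔVm/Δt`, their ratio, and the normalized area
  under the AP (triangulation indices);
* rate-dependence statistics `ΔAPD_short − ΔAPD_long` with
  reverse/positive classification, and a canonical particle swarm optimizer
  over `(sKs, sKr, sK1)` minimizing `(ΔAPD_long − ΔAPD_short) +
  λ·|APD_long − goal|`.

## Worked example

Compare 73% IK1 block against the optimizer's reference combination
(2·IKs, 0.3·IKr, 0.2·IK1), both of which prolong the control APD
(305.4 ms at BCL 3000 ms) to ~330 ms:

```r
library(apratedep)

ctl   <- restitution(scaled_params(),            bcls = c(400, 3000))
k1b   <- restitution(scaled_params(sK1 = 0.27),  bcls = c(400, 3000))
combo <- restitution(scaled_params(2, 0.3, 0.2), bcls = c(400, 3000))

rate_dependence(k1b$apd90[2],   k1b$apd90[1],
                ctl$apd90[2],   ctl$apd90[1])
#> <rate_dependence> dAPD(long)=25.1 dAPD(short)=46.5 ms, rd_index=21.5 ms
#>   (positive), shortening=23.8%
rate_dependence(combo$apd90[2], combo$apd90[1],
                ctl$apd90[2],   ctl$apd90[1])
#> <rate_dependence> dAPD(long)=25.5 dAPD(short)=82.7 ms, rd_index=57.3 ms
#>   (positive), shortening=13.0%
```

Both interventions hit the same APD goal at slow pacing (330.5 and 330.9 ms),
but the combination prolongs 82.7 ms at BCL 400 versus 46.5 ms for IK1 block
alone — a far stronger positive rate dependence (rd_index 57.3 vs 21.5 ms)
and less APD shortening at fast rate (13.0% vs 23.8%). The shape features
behind this (`extract_features()` on the paced beat) show the combination's
more triangular AP: faster phase-2 repolarization, slower phase 3, smaller
phase-3/phase-2 current ratio and smaller normalized area. On the control
beat the phase-2/3 boundary (IK1 at 10% of peak) sits at −25.3 mV.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the steady-state
reference quantities: APD90 at BCL 3000 ms for the five printed
single-channel and combined interventions, the slow-vs-fast APD shortening
of the (2, 0.41, 0.2) combination, the membrane potential at the control
phase-2/3 boundary, and the 16-vs-32-minute steady-state APD drift, writing
one JSON number per target (runtime ≈ 4 min).
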
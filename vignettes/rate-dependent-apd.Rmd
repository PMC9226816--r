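---
title: "Rate-dependent APD prolongation by potassium channel modulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-dependent APD prolongation by potassium channel modulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Class III antiarrhythmic agents prolong the ventricular action potential
duration (APD), and with it the refractory period, to interrupt reentrant
arrhythmias. Their clinical weakness is *reverse rate dependence*: blocking a
single potassium channel prolongs the APD more at slow pacing rates than at
the fast rates typical of ventricular tachycardia, which is the opposite of
what an antiarrhythmic drug should do. This package simulates a human
ventricular epicardial myocyte and asks which *combinations* of potassium
channel interventions — enhancing the slow delayed rectifier IKs while
blocking the rapid delayed rectifier IKr and the inward rectifier IK1 —
prolong APD with a *positive* rate dependence, and what that costs in
repolarization reserve.

The quantities of interest, for an intervention $X$ against control $C$ at a
long and a short basic cycle length (BCL, default 3000 and 400 ms):

* $\Delta APD_{long} = APD^X_{3000} - APD^C_{3000}$ and likewise
  $\Delta APD_{short}$ at BCL 400 ms;
* the rate-dependence index $\Delta APD_{short} - \Delta APD_{long}$
  (positive = positive rate dependence, negative = reverse);
* percentage APD shortening
  $100\,(APD_{3000} - APD_{400})/APD_{3000}$;
* shape features of the AP (below) that correlate with the rate dependence.

## The ionic model

The default cell is the ten Tusscher–Noble–Noble–Panfilov (2004) human
ventricular **epicardial** myocyte as distributed on the CellML repository,
exposed as the registered model `"tnnp2004epi"`. The three repolarizing
potassium conductances are scalable through dimensionless multipliers
(`sKs`, `sKr`, `sK1` in `scaled_params()`), with allowed ranges
$s_{Ks}, s_{Kr} \in [0, 2]$ and $s_{K1} \in [0.2, 2]$; multipliers of exactly
1 reproduce the unmodified published model. All currents are normalized to
membrane capacitance (pA/pF, outward positive) and the single-cell membrane
equation is $dV_m/dt = -(I_{ion} + i_{stim})$.

Two revisions of this cell exist and the package ships both. The 2006
revision (`"tnnp2006epi"`) carries a much larger maximal IKs
(0.392 vs 0.245 nS/pF) and a larger maximal IKr (0.153 vs 0.096 nS/pF).
This matters: with the 2006 parameterization, doubling IKs over-shortens the
plateau so strongly that the reference intervention
$2(I_{Ks}) + 0.3(I_{Kr}) + 0.2(I_{K1})$ cannot reach a 330 ms APD at
BCL 3000 ms, while with the 2004 cell it lands within about a millisecond of
it — as do all the single-channel APD goals we test. The package therefore
uses the 2004 cell as the default and acceptance model; the 2006 cell remains
available behind the same plugin interface (`register_model()` /
`get_model()`), which is also the extension point for other published models.

### Numerics

* **Integration**: Rush–Larsen exponential updates for all Hodgkin–Huxley
  gating variables (an unconditionally stable convex combination, so gates
  stay in $[0,1]$), forward Euler for $V_m$ and the ionic concentrations,
  fixed $dt = 0.02$ ms. The test suite asserts that halving $dt$ moves
  late-beat APD90 by well under half a millisecond.
* **Fast path**: pacing uses lookup tables on a 0.01 mV grid for the gate
  steady states, the Rush–Larsen factors $e^{-dt/\tau(V)}$ and the purely
  voltage-dependent current factors, rebuilt when `dt` changes. A table-free
  exact path backs `derivatives()`/`currents()`; the suite asserts both paths
  agree to $10^{-7}$ per step. Linear interpolation error at this grid is
  far below every tolerance used.
* **The calcium-dependent gates** of the 2004 cell (`fCa`, `g`) follow the
  published conditional rule: they relax exponentially toward their targets
  but may not increase while the membrane is depolarized above −60 mV.
* **Traces** are recorded every 0.1 ms regardless of `dt`, as
  `time_ms, Vm_mV, IKs, IKr, IK1, Iion` CSV; the first row of a beat trace is
  the pre-stimulus sample, so the takeoff potential is always available.
* **Determinism**: there is no randomness anywhere in the simulator; repeated
  runs are byte-identical. Only the particle swarm uses a seeded RNG.

## Stimulation protocols

An action potential is "captured" when $V_m$ overshoots 0 mV within 10 ms of
stimulus onset. The stimulation threshold is the minimal 1-ms rectangular
pulse amplitude eliciting capture from rest, found by bisection to 1%
relative tolerance (`find_threshold()`); pacing always uses 1.5× threshold,
re-determined per conductance set because IK1 scaling moves the threshold.
The 1-ms pulse duration is a package choice (conventional for this model
family); the stimulus current is included in the intracellular K⁺ balance,
as in the published source of the model.

`pace()` paces each BCL independently from the published initial conditions
for 16 simulated minutes (the package's steady-state convention: the suite
checks that APD90 at 16 min is within 1 ms of a 32-min run), returning the
final beat with capture and alternans diagnostics (alternans:
$|APD_n - APD_{n-1}| > 2$ ms on the last beat pair). The final beat is
measured, not an average of late beats.

`repolarization_reserve()` estimates the pro-arrhythmic cost of an
intervention: re-run the steady-state beat with an extra constant
depolarizing current (default −0.1 pA/pF, emulating an enhanced persistent
inward current) applied from the stimulus onset until the beat repolarizes
to its APD90, and report the percentage APD prolongation. Injection starts
at stimulus onset rather than at the upstroke proper; the difference is
about a millisecond of −0.1 pA/pF during diastolic potential, which is
negligible against the AP-long injection window. Failure to repolarize
within one cycle is reported as infinite prolongation (no reserve).

## Action potential features

Phases are delimited by current-based landmarks, interpolated linearly
between samples:

* **phase 1** runs from the upstroke (maximum $dV_m/dt$) to the first
  negative-to-positive sign change of $I_{ion}$ — the instant net
  repolarization begins;
* **phase 2** ends when IK1 first reaches 10% of its peak over the
  repolarization window (searched after the phase-1 end to avoid any
  stimulus artifact). On the control beat this lands near −25 mV; under
  heavy IK1 block the *rule*, not the voltage, is authoritative;
* **phase 3** ends at 90% repolarization of the AP amplitude (APD90).

Because a single cell carries no axial current, the average total ionic
current over any interval is the negative slope of the chord of $V_m$:
$\bar I_{ion}/C_m = -(V_{m,t_2} - V_{m,t_1})/(t_2 - t_1)$. The phase-2 and
phase-3 average currents use this identity (`avg_ionic_current()`), and the
suite checks it against direct quadrature of the recorded $I_{ion}$ to 0.5%.
Their ratio and the normalized area under the AP
(`auap_norm` = area above the takeoff potential from upstroke to APD90,
divided by APD90 × APA) are triangulation indices: positively rate-dependent
APs are more triangular (smaller ratio, smaller area).

A definitional footnote: for an idealized triangle that decays linearly from
peak to baseline, the area index under these operative definitions is
0.495/0.9 = **0.55**, not the naive half-area 0.5, because the integral and
the normalization stop at the 90%-repolarization time. The fixture
generator's stored ground truth uses the operative value.

## Synthetic fixtures

`generate_fixture()` builds piecewise-linear idealized traces (rectangle,
triangle, trapezoid, and a stylized AP with placed phase landmarks) whose
features are known in closed form, including an `Iion` column that is the
exact negative slope and, for the AP shape, an IK1 ramp whose 10%-of-peak
crossing sits exactly at the requested phase-2 end. They exercise the
feature extractor without the ionic model, so a green feature test
establishes the extractor's correctness on known geometry — it says nothing
about the ionic model, whose own tests compare against an independent
transcription of the published equations and against charge conservation.
The fixtures deliberately do not emulate stimulus artifacts, noise, or
sampling jitter of experimental recordings.

## The conductance search

`optimize_conductances()` runs a canonical particle swarm (velocity
$v \leftarrow w v + c_1 r_1 (p - x) + c_2 r_2 (g - x)$, positions clamped to
bounds) over $(s_{Ks}, s_{Kr}, s_{K1})$, minimizing

$$(\Delta APD_{long} - \Delta APD_{short}) \;+\; \lambda \,|APD_{long} - \text{goal}|.$$

Unstated upstream, chosen here: Clerc–Kennedy constriction-equivalent
hyperparameters ($w = 0.7298$, $c_1 = c_2 = 1.49618$), 20 particles × 60
iterations by default, and a linear goal penalty with $\lambda = 10$ per ms
— large enough that the APD goal binds (a 1-ms miss outweighs the largest
observed rate-dependence differences per ms), small enough that the
rate-dependence term decides among goal-satisfying combinations. Capture
loss, alternans or repolarization failure at either BCL scores a large
constant (1e4). Objective evaluations are memoised with multipliers rounded
to 3 decimals. The protocol knob mirrors the reserve trade-off: the lower
bound on $s_{K1}$ is raised through 0.2/0.5/0.7/1.0 to restrict IK1 block.

**Scaled-down search mode.** A full-fidelity objective evaluation costs two
16-minute pacing runs. For test-budget searches, `objective_spec(...,
warm_start = TRUE, minutes = c(0.25, 0.1))` paces each candidate briefly
*from the control steady state at that BCL* (itself always paced the full
16 minutes, once, and cached). Plain shortened pacing from initial
conditions is not a valid shortcut here — it leaves the slow ionic drift in
place, the APD-goal surface shifts by tens of ms at fractions of a minute,
and the search degenerates; the warm start removes most of the drift on the
goal side (the short-BCL side keeps a larger bias, which compresses but does
not reorder the rate-dependence differences). Because a test-budget swarm is
too small to explore the multimodal goal-penalty landscape reliably, the
scaled search is coarse-to-fine: a 5×5×5 grid scan over cached simulations
seeds the swarm's first particles (plus, when the $s_{K1}$ bound is raised,
the projection of the previous optimum — plain continuation), and the swarm
refines from there. Optima are re-scored at full 16-minute fidelity before
any conclusion is drawn. The acceptance suite asserts structure — the active
$s_{K1}$ bound, the rate-dependence/reserve trade-off as the bound rises,
and that the swarm does at least as well as the grid oracle — not absolute
objective values. The full-fidelity default (20 particles × 60 iterations,
no seeding) is the canonical unseeded algorithm.

## Configuration files

Experiment configs are declarative JSON (`read_experiment_config()`)
mirroring `experiment_config()`: labelled multiplier triples, BCL list,
pacing length, optional reserve and optimization stages. JSON rather than
YAML because the pinned R environment carries no YAML parser; the structure
is unchanged.

## Known limitations

* Single cell only: no tissue coupling, electrotonic loading, or
  propagation, so conclusions about reentry are indirect.
* No beta-adrenergic signaling; fast rates are imposed by pacing alone.
* The rate-dependence *sign* of a single intervention can sit within a few
  ms of zero (59% IKr block is such a case); at that margin the
  classification is sensitive to reimplementation details at the
  millisecond level even when all absolute APDs agree.
* The ToR-ORd model is not shipped; the plugin interface
  (`register_model()`) defines the contract a port must satisfy.
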
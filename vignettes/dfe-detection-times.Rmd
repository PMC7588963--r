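---
title: "Modelling blood detection times of 1,1-difluoroethane after inhalation abuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling blood detection times of 1,1-difluoroethane after inhalation abuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(dfemdt)
```

## The problem

1,1-Difluoroethane (DFE, HFC-152a) is the propellant in most "air duster"
spray cans and a common inhalant of abuse. It is a volatile gas with low
blood solubility, so it is cleared from blood within hours of use, and
clinicians rarely order a blood test because the detection window is
poorly characterized. `dfemdt` estimates that window — the *maximum
detection time* (MDT), the time from the end of an abuse session until
venous blood falls below an analytical detection limit — by simulating
huffing sessions with a physiologically based pharmacokinetic (PBPK) model
and propagating population variability by Monte Carlo simulation.

## The PBPK model

The body is represented by five well-mixed compartments: a combined
lungs-plus-arterial-blood pool, the rapidly perfused organs (VRG), fat,
muscle, and liver. Uptake and elimination are exclusively pulmonary: DFE
metabolism in humans is negligible, and no metabolic term appears anywhere.
All exchange is perfusion-limited. Writing $A_i$ for the amount (mg) in
compartment $i$, $V_i$ (L) its volume, $Q_i$ (L/min) its blood flow,
$P_i$ its tissue:blood partition coefficient, and $P_{ba}$ the blood:air
partition coefficient:

$$
\frac{dA_L}{dt} = Q_{alv}\left(C_{inh} - \frac{C_{art}}{P_{ba}}\right)
 + \sum_i Q_i \left(\frac{C_i}{P_i} - C_{art}\right), \qquad
\frac{dA_i}{dt} = Q_i\left(C_{art} - \frac{C_i}{P_i}\right),
$$

with $C_{art} = A_L / (V_L P_L)$ the blood concentration leaving the lung
pool, $C_i = A_i / V_i$, and the mixed venous concentration — the quantity
compared against detection limits — the flow-weighted mean of the tissue
outflows, $C_{ven} = \sum_i Q_i (C_i/P_i) / \sum_i Q_i$.

Two details are worth making explicit:

* The combined lungs/arterial pool is treated as a single well-mixed
  compartment whose outflow concentration uses the lung:blood coefficient
  and whose equilibrium air concentration divides further by the blood:air
  coefficient. This is the simplest structure that uses both coefficients
  of the reference parameter set.
* The reference table prints a cardiac output of 6.32 L/min while its
  tissue flows sum to 6.33 L/min. The rate matrix uses the tissue-flow sum
  for both the lung-blood throughput and the venous mixing denominator, so
  mass is conserved exactly; the printed 6.32 is retained as the `q_co`
  field and the package checks flow conservation to within 0.5%.

The standard man (70 kg, 1.70 m, BMI 24.2, 10 W workload) is parameterized
by `standard_man()`; every constant lives in the shipped YAML configuration
(`inst/extdata/dfemdt-config.yaml`). The implied washout time constants
$V P / Q$ are about 0.8 min for VRG and liver, 20.3 min for muscle, and
3.0 h for fat, which is why the post-session decline shows three phases
and why the terminal phase — the one that sets the MDT at low detection
limits — is governed by fat.

```{r}
sm <- standard_man()
c(vrg = washout_time_constant(sm, "vrg"),
  liver = washout_time_constant(sm, "liver"),
  muscle = washout_time_constant(sm, "muscle"),
  fat_h = washout_time_constant(sm, "fat") / 60)
```

The muscle value deserves a note: descriptions of the intermediate washout
phase in the forensic literature quote a half time of 41 min, while the
reference volumes and flows give $V P / Q = 20.3$ min (and 14.1 min if a
$\ln 2$ factor is applied). The two cannot be reconciled from the printed
parameter set; `dfemdt` reports the value computed from its own parameters.
For VRG, liver, and fat the quoted half times match $V P / Q$ with no
$\ln 2$ factor, and that convention is used throughout.

## Anthropometric scaling

Population variability in body build enters through BMI. Height is held at
1.70 m, so body weight is $BW = BMI \times H^2$. Compartment volumes and
flows scale as:

* **Fat**: body fat fraction is linear in BMI, $f = a \cdot BMI + b$ with
  $a = 0.012$ per BMI unit — the slope of standard adult-male body-fat
  regressions — and $b$ solved so that BMI 24.2 at 1.70 m returns exactly
  the reference 15.43 L of fat (fat density 0.92 kg/L). Fat volume is then
  $f \cdot BW / 0.92$.
* **Lean tissues** (lung pool, VRG, muscle, liver): proportional to lean
  body mass $BW(1 - f)$, normalized to the reference values.
* **Cardiac output and alveolar ventilation**: proportional to lean body
  mass to the 3/4 power (the usual allometric exponent for metabolically
  driven flows), normalized to the reference values.
* **Tissue flows**: fixed fractions of cardiac output, taken from the
  reference table. A consequence is that the fat washout time constant
  $V_f P_f / Q_f$ grows steeply with BMI, which produces the strong BMI
  dependence of the post-session decline that motivates the Monte Carlo
  analysis in the first place.
* **Workload**: ventilation and cardiac output gain 0.1 L/min per W above
  the 10 W resting baseline, routed to muscle. Only the sensitivity
  analysis exercises this pathway; its slope is the least-constrained
  number in the package and affects nothing else.

Everything is anchored so that `scale_physiology(24.2, 1.70, 10)` equals
`standard_man()` to machine precision; an acceptance-level test asserts
this, along with strict monotonicity of fat volume and the fat time
constant over BMI 16.5–40 and flow conservation for every scaled subject.

## Exposure scenarios

Two huffing scenarios, derived from user interviews, drive the
simulations: scenario X — 6-h session, inhalations of 1.5–8 s every 3–5
min — and scenario Y — 2-h session, 5–15 s every 2–5 min — both of
essentially pure DFE (1,000,000 ppm, i.e. 2701.4 mg/L of air at 25 °C).
The stated inhalation windows merge the inhalation proper with the
subsequent breath-hold, and the model treats the whole window as breathing
pure DFE at the nominal alveolar ventilation; ventilation is not
suppressed between huffs. The first huff starts at $t = 0$ and every huff
whose start falls before the nominal session end is included in full.
These conventions are deliberate simplifications of behaviour that the
interview ranges already blur; their main effect is a modest upward bias
of the delivered dose (see *Limitations*).

## Population sampling

Each simulated subject draws one BMI from a normal distribution with mean
25.8 and SD 3.43 kg/m² — a fit to adult-male US survey data — truncated by
rejection sampling to [16.5, 40], and one huff pattern (duration and cycle
uniform over the scenario ranges). Draws are per subject, not per huff:
the early post-session spread between subjects reflects between-person
differences in inhalation behaviour, which a per-huff redraw would average
away. A `per_huff = TRUE` mode exists for exploration. One seeded RNG
stream drives all draws in subject order, so an ensemble is a pure
function of `(population, scenario, seed)`.

The truncated-normal sampler is checked against the closed-form mean
(`truncated_bmi_mean()`, 25.83 for the default parameters).

## Solvers and numerical choices

The model is linear with piecewise-constant input, so it has an exact
solution: within each exposure segment, `dfemdt` propagates the state
through the eigendecomposition of the $5 \times 5$ rate matrix, evaluating
concentrations (and the integral that tracks cumulative exhaled mass) in
closed form at arbitrary output times. This is the default solver and the
one ensembles use; its mass-balance error is at machine precision and a
1000-subject ensemble takes seconds. A fixed-step classical Runge–Kutta
integrator (default step 0.5 s during the session to resolve the
square-wave huffs, 6 s afterwards, never straddling an exposure switch) is
provided as an independent numerical route; tests require agreement with
the closed form within 0.1% and verify the expected fourth-order error
decay.

Other numerical conventions:

* Internal units: minutes, mg, L.
* Output grid: 0.1 min during the session, 1 min after; single-subject
  simulations run to session end + 36 h, ensembles to + 72 h so that even
  the highest-BMI subjects cross the lowest detection limit (0.018 mg/L)
  before the horizon.
* MDT crossing: the sampled trajectory is scanned from its end and the
  crossing interpolated linearly in log-concentration, exact for
  exponential decay. A trajectory still above the limit at its final
  sample raises an error rather than returning a truncated value.
* Quantiles: linear interpolation between order statistics (R type 7).
* Percentile curves: trajectories are smoothed during the session with a
  centered 5-min moving average (configurable; roughly one huff cycle) to
  remove between-huff fluctuations, and left unsmoothed afterwards.

## Sensitivity analysis

`sensitivity_analysis()` computes normalized local sensitivity
coefficients — percent change in venous DFE per percent change in a
parameter — for venous blood at 24 h on the standard-man scenario-Y
central pattern (10-s huffs every 3.5 min), by central differences with a
1% perturbation (checked robust between 0.5% and 2%). Body weight, BMI,
and workload are perturbed upstream of the scaling chain, so their
coefficients include all induced volume and flow changes; with height
fixed, BW and BMI are the same pathway and return identical coefficients.
The fat-related parameters (BMI/BW, fat volume, fat:blood partition, fat
blood flow) dominate late blood levels, and alveolar ventilation matters
comparatively little — the pattern that motivates sampling BMI, and not
ventilation, in the Monte Carlo ensemble.

```{r}
sensitivity_analysis(parameters = c("Vf", "PCfb", "Qfat", "Qalv", "Vm"))
```

## What the generator emulates — and what it does not

The exposure/population generator reproduces exactly the stated study
conditions: uniform inhalation-pattern variability within the interview
ranges, truncated-normal BMI variability, fixed height and near-rest
workload, adult-male physiology. It does **not** emulate several features
of real abuse: variability in fat perfusion (known to be wide, and which
would widen the MDT ranges), within-session changes in breathing or
circulation at intoxicating exposure levels, rebreathing from bags,
female or adolescent physiology, or any metabolic clearance. Passing
tests therefore demonstrate fidelity to the stated model and population,
not validity of extrapolation beyond them.

## Known limitations

* **Reported detection-time tables are not fully reproducible from the
  printed model.** Published MDT estimates for these two scenarios place
  the 6-h scenario ~3 h above the 2-h scenario at every detection limit,
  and their spacing between the 0.14 and 0.018 mg/L limits implies an
  effective terminal time constant of ~2.5 h. Both conflict with the
  printed kinetics themselves: the reference parameters give a 3.0-h fat
  time constant, and a linear perfusion-limited model whose 6-h scenario
  plateaus near 40 mg/L cannot hold a fat-phase venous intercept large
  enough to produce the reported 6-h-scenario values while also producing
  the 2-h-scenario ones. `dfemdt` reproduces the washout constants, the
  session concentration levels and ratio, and the extreme MDTs (2-h
  scenario at 5.4 mg/L; 6-h scenario at 0.018 mg/L), but its 2-h-scenario
  medians at 0.14 mg/L run ~2 h above the reported 10.5 h and its
  percentile ranges are wider. The discrepancies are reported as computed.
* The anthropometric scaling scheme is a documented reconstruction
  anchored at the standard man, not the original (unpublished in full)
  scaling equations; the fat-fraction slope controls how strongly MDT
  spreads with BMI.
* Exposure conventions (merged inhalation + breath-hold at full
  ventilation) bias delivered dose upward by a factor that cannot be
  resolved from interview data; session-average concentrations land in
  the upper half of the reported ±30% band.
* MDTs assume venous (capillary) blood sampling and instantaneous,
  loss-free analysis; real specimens lose volatiles.

## Reproducing the study-scale results

`scripts/acceptance.R` in the source repository reruns the whole pipeline
(two 1000-subject ensembles, the deterministic standard-man run, and the
washout arithmetic) from a command-line seed and writes the headline
numbers as JSON. The testthat suite runs the same checks at 500 subjects.
On one CPU the script takes well under a minute.
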
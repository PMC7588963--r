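# dfemdt

PBPK Monte Carlo estimation of how long 1,1-difluoroethane (DFE,
HFC-152a) — the propellant in "air duster" spray cans and a common
inhalant of abuse — remains detectable in blood after a huffing session.

Clinicians treating inhalant use disorder rarely test for DFE because the
detection window is unknown: the gas has low blood solubility and is
cleared within hours. `dfemdt` estimates the **maximum detection time
(MDT)** — the time from the end of an abuse session until venous blood
falls below an analytical limit — for a simulated adult-male population,
and reports it as a median with 5th–95th percentile range per detection
limit and exposure scenario.

## The model

A five-compartment perfusion-limited PBPK model (combined lungs +
arterial blood, rapidly perfused organs, fat, muscle, liver) with purely
pulmonary uptake and elimination and zero metabolism:

$$\frac{dA_L}{dt} = Q_{alv}\,(C_{inh} - C_{art}/P_{ba}) + \textstyle\sum_i Q_i\,(C_i/P_i - C_{art}),
\qquad \frac{dA_i}{dt} = Q_i\,(C_{art} - C_i/P_i)$$

The mixed venous concentration $C_{ven} = \sum_i Q_i (C_i/P_i) / \sum_i
Q_i$ is compared against blood detection limits (0.018, 0.14, 5.4 mg/L).
Exposure is a square wave of pure DFE (2701.4 mg/L air) during brief
huffs: scenario X is a 6-h session with 1.5–8-s inhalations every 3–5
min, scenario Y a 2-h session with 5–15-s inhalations every 2–5 min.
Monte Carlo variability enters through per-subject uniform draws of the
inhalation pattern and a truncated-normal BMI (mean 25.8, SD 3.43,
bounds 16.5–40 kg/m²) that rescales compartment volumes and flows, so
that fatter subjects store more DFE and wash it out more slowly
(fat washout time constant $V_f P_f / Q_f \approx 3$ h at BMI 24.2).

Because the system is linear with piecewise-constant input, trajectories
are propagated **exactly** (per-segment eigendecomposition); a fixed-step
RK4 solver is included as an independent cross-check. See the methods
vignette (`vignettes/dfe-detection-times.Rmd`) for the full model,
scaling scheme, and numerical conventions.

## Worked example

```r
library(dfemdt)

# one deterministic subject: standard man, scenario-Y central pattern
sc   <- exposure_scenario("Y")
traj <- simulate_pbpk(standard_man(),
                      inhaled_concentration_profile(central_pattern(sc), sc))
glance(traj)
#> # A tibble: 1 × 6
#>   n_times session_min peak_c_ven session_avg_c_ven mass_balance_error solver
#>     <int>       <dbl>      <dbl>             <dbl>              <dbl> <chr>
#> 1    3361         120       250.              123.           8.37e-16 closed_form

maximum_detection_time(traj, limit = 0.14)
#> [1] 11.86153

# Monte Carlo: 500 subjects with BMI and huff-pattern variability
ens <- run_ensemble("Y", n = 500, seed = 42)
summarize_mdt(ens)
#>   detection_limit_mg_per_l scenario median_h  p5_h p95_h   n seed
#> 1                    0.018        Y    19.95 13.15 28.01 500   42
#> 2                    0.140        Y    12.75  8.50 18.17 500   42
#> 3                    5.400        Y     1.27  0.68  2.58 500   42

autoplot(ens)              # percentile curves vs detection limits
sensitivity_analysis()     # which parameters drive late blood levels
```

Reading the output: during the 2-h session venous DFE fluctuates around
~120 mg/L (peaks ~250 mg/L during huffs); after the session it declines
in three phases (richly perfused organs, muscle, fat), and at the 0.14
mg/L laboratory reporting limit the median simulated subject stays
detectable for ~13 h, with a 5th–95th percentile range of ~8–18 h driven
mostly by body fat. A blood test several hours after suspected use is
therefore still informative.

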
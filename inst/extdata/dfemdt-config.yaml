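# Default model configuration for dfemdt.
# Standard-man physiology (resting adult male, 70 kg, 1.70 m, BMI 24.2, 10 W),
# the two huffing exposure scenarios, blood detection limits, and the BMI
# population distribution. All numeric values below are the package's
# reference parameterization; scale_physiology() is anchored to reproduce the
# standard-man block exactly.
version: 1
substance:
  name: "1,1-difluoroethane (DFE, HFC-152a)"
  molecular_weight_g_mol: 66.05
  molar_volume_l_mol: 24.45   # 25 C, 1 atm
standard_man:
  body_weight_kg: 70
  height_m: 1.70
  bmi_kg_m2: 24.2
  workload_w: 10
  alveolar_ventilation_l_min: 8.90
  cardiac_output_l_min: 6.32
  pc_blood_air: 1.08
  compartments:
    lung_arterial: {volume_l: 1.44, flow_l_min: 6.32, pc_tissue_blood: 1.24}
    vrg:           {volume_l: 2.09, flow_l_min: 3.20, pc_tissue_blood: 1.24}
    fat:           {volume_l: 15.43, flow_l_min: 0.34, pc_tissue_blood: 3.94}
    muscle:        {volume_l: 17.45, flow_l_min: 1.15, pc_tissue_blood: 1.34}
    liver:         {volume_l: 1.48, flow_l_min: 1.64, pc_tissue_blood: 0.88}
scaling:
  # body fat fraction = slope * BMI + intercept; intercept solved at load time
  # so that BMI 24.2 at 1.70 m gives exactly the standard-man fat volume
  fat_fraction_slope_per_bmi: 0.012
  fat_density_kg_l: 0.92
  lean_flow_exponent: 0.75
  workload_flow_slope_l_min_per_w: 0.1
  bmi_model_range: [10, 60]
scenarios:
  "X":
    inhaled_concentration_ppm: 1000000
    session_duration_h: 6
    inhalation_duration_s: [1.5, 8]
    cycle_min: [3, 5]
  "Y":
    inhaled_concentration_ppm: 1000000
    session_duration_h: 2
    inhalation_duration_s: [5, 15]
    cycle_min: [2, 5]
detection_limits_mg_l:
  - {value: 0.018, label: "LOD, GC/MS"}
  - {value: 0.14,  label: "LOQ, accredited lab reporting limit"}
  - {value: 5.4,   label: "evidence of intentional inhalation"}
population:
  bmi_mean: 25.8
  bmi_sd: 3.43
  bmi_bounds: [16.5, 40]
  height_m: 1.70
  workload_w: 10
simulation:
  post_session_horizon_h: 36
  session_output_dt_min: 0.1
  post_output_dt_min: 1
  rk4_session_step_s: 0.5
  rk4_post_step_s: 6
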
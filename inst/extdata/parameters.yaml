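# Default model inputs: published unit costs, utilities, annual transition
# rates and adverse-event profiles for the rituximab (RTX) vs tacrolimus
# (TAC) comparison in primary membranous nephropathy, plus the model
# settings. Ranges, where printed, are read as 95% intervals when fitting
# Beta/Gamma sampling distributions; entries without a range are fixed in
# PSA and varied +/-20% in one-way DSA. All costs in yuan (CNY).

settings:
  cycle_length_days: 30
  cycles_per_year: 12
  horizon_years: 5
  max_horizon_years: 5
  discount_rate: 0.05
  gdp_per_capita: 85698
  wtp_per_qaly: 257094
  default_range_fraction: 0.20
  body_surface_area_m2: 1.73
  body_weight_kg: 60
  rtx_vial_mg: 100
  rtx_dose_mg_per_m2: 375
  rtx_doses_per_induction: 4
  rtx_second_course_cycle: 6
  tac_treatment_cycles: 12
  tac_steroid_start_mg_per_kg: 0.4   # methylprednisolone-equivalent of prednisolone 0.5 mg/kg/d
  tac_steroid_taper_start_cycle: 3   # taper begins after 8 weeks
  tac_steroid_taper_step_mg: 4       # per cycle, methylprednisolone-equivalent of 5 mg prednisolone
  tac_steroid_maintenance_mg: 8      # equivalent of prednisolone 10 mg/d
  half_cycle_correction: false
  relapse_utility: active_disease   # no published relapse utility; shares active disease
  monitoring_cycles: [1, 3, 6, 9, 12]

transition_rates:          # annual probabilities unless time_basis says otherwise
  pd_to_hd:           {mean: 0.1633}
  hd_to_pd:           {mean: 0.0032}
  dialysis_incidence: {mean: 0.0002}      # redundant aggregate; loaded, unused
  hd_incidence:       {mean: 0.0002}
  pd_incidence:       {mean: 0.00003}
  kt_incidence:       {mean: 0.0794}
  hd_to_death:        {mean: 0.0422}
  pd_to_death:        {mean: 0.0388}
  kt_mortality:       {mean: 0.425, low: 0.35, high: 0.50, family: beta,
                       time_basis: per_10_years}

utilities:
  complete_remission:  {mean: 0.86,  low: 0.63,  high: 1.00, family: beta}
  partial_remission:   {mean: 0.86,  low: 0.63,  high: 1.00, family: beta}
  active_disease:      {mean: 0.738, low: 0.422, high: 1.00, family: beta}
  esrd:                {mean: 0.80,  low: 0.65,  high: 0.94, family: beta}  # unused
  conservative:        {mean: 0.62,  low: 0.36,  high: 0.89, family: beta}  # unused
  hemodialysis:        {mean: 0.68,  low: 0.53,  high: 0.82, family: beta}
  peritoneal_dialysis: {mean: 0.71,  low: 0.59,  high: 0.82, family: beta}
  kidney_transplant:   {mean: 0.82,  low: 0.74,  high: 0.90, family: beta}
  death:               {mean: 0.0, family: fixed}

ae_incidence:              # per treatment course
  rtx:
    rash:                   {mean: 0.0377, low: 0.030, high: 0.045, family: beta}
    fever:                  {mean: 0.0189, low: 0.015, high: 0.023, family: beta}
    gi_infection:           {mean: 0.0189, low: 0.015, high: 0.023, family: beta}
    pneumonia:              {mean: 0.0189, low: 0.015, high: 0.023, family: beta}
  tac:
    severe_pneumonia:       {mean: 0.1143, low: 0.091, high: 0.137, family: beta}
    lung_abscess:           {mean: 0.0286, low: 0.023, high: 0.034, family: beta}
    interstitial_pneumonia: {mean: 0.0286, low: 0.023, high: 0.034, family: beta}
    hyperglycemia:          {mean: 0.1429, low: 0.114, high: 0.171, family: beta}

ae_costs:                  # yuan per event; severe pneumonia priced as pneumonia
  rash:                   {mean: 44.3751,   low: 35.500,   high: 53.250,   family: gamma}
  fever:                  {mean: 33.3,      low: 26.640,   high: 39.960,   family: gamma}
  gi_infection:           {mean: 425.0545,  low: 340.043,  high: 510.064,  family: gamma}
  pneumonia:              {mean: 7400.0,    low: 5920.0,   high: 8880.0,   family: gamma}
  severe_pneumonia:       {mean: 7400.0,    low: 5920.0,   high: 8880.0,   family: gamma}
  lung_abscess:           {mean: 10000.0,   low: 8000.0,   high: 12000.0,  family: gamma}
  interstitial_pneumonia: {mean: 4000.0,    low: 3200.0,   high: 4800.0,   family: gamma}
  hyperglycemia:          {mean: 15.0,      low: 12.0,     high: 18.0,     family: gamma}

direct_costs:
  hemodialysis_annual:        {mean: 40678.0,  low: 32542.400, high: 48813.600, family: gamma}
  peritoneal_dialysis_annual: {mean: 31145.0,  low: 24916.000, high: 37374.000, family: gamma}
  kidney_transplant_annual:   {mean: 10278.8,  low: 8223.040,  high: 12334.560, family: gamma}
  rtx_vial:                   {mean: 1366.2,   low: 1093.0,    high: 1639.0,    family: gamma}
  tac_6mo_cr:                 {mean: 9976.0,   low: 7980.800,  high: 11971.200, family: gamma}
  tac_6mo_pr:                 {mean: 9976.0,   low: 7980.800,  high: 11971.200, family: gamma}
  tac_6mo_nr:                 {mean: 10626.0,  low: 8500.800,  high: 12751.200, family: gamma}
  tac_6mo_relapse:            {mean: 10626.0,  low: 8500.800,  high: 12751.200, family: gamma}
  methylprednisolone_4mg_tab: {mean: 0.878,    low: 0.702,     high: 1.054,     family: gamma}
  urinalysis:                 {mean: 47.0,     low: 37.60,     high: 56.40,     family: gamma}
  rapid_proteinuria_test:     {mean: 44.0,     low: 35.20,     high: 52.80,     family: gamma}
  quant_proteinuria_test:     {mean: 9.0,      low: 7.20,      high: 10.80,     family: gamma}
  liver_function_test:        {mean: 55.0,     low: 44.00,     high: 66.00,     family: gamma}

# 12-month outcome counts used to calibrate remission/relapse transitions
# and, in PSA, to derive binomial uncertainty for those targets.
outcome_targets:
  rtx: {size: 53, cr: 34, pr: 12, nr: 5, relapse: 2}
  tac: {size: 35, cr: 8,  pr: 17, nr: 10, relapse: 8}
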
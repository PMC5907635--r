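# Base-case parameterization: adverse-event probabilities, treatment
# pathway, utilities, resource use and unit costs (GBP, 2015-2016).
# Network-meta-analysis mean differences (episodes/day vs the reference
# drug) are documented synthetic stand-ins, as are the baseline severity
# distribution (truncated-geometric marginals), the severity midpoints and
# the base utility of the worst health state; the supplementary sources for
# those quantities are not deposited. DSA entries are [low, high] ranges.
schema_version: "1.0"

drugs:
  solifenacin_5mg:
    monthly_cost: 28.00
    is_reference: true
    ae_prob_3m: {dry_mouth: 0.143, constipation: 0.072}
    discontinuation_monthly_no_ae: 0.068
    nma_mean_diff: {micturitions_per_day: 0.0, incontinence_per_day: 0.0}
    dsa:
      ae_prob_3m.dry_mouth: [0.102, 0.184]
      ae_prob_3m.constipation: [0.042, 0.102]
      discontinuation_monthly_no_ae: [0.034, 0.102]
  tolterodine_er_4mg:
    monthly_cost: 28.01
    ae_prob_3m: {dry_mouth: 0.149, constipation: 0.043}
    discontinuation_monthly_no_ae: 0.068
    nma_mean_diff: {micturitions_per_day: 0.20, incontinence_per_day: 0.05}
    dsa:
      ae_prob_3m.dry_mouth: [0.128, 0.178]
      ae_prob_3m.constipation: [0.030, 0.062]
      discontinuation_monthly_no_ae: [0.034, 0.102]
      nma_mean_diff.micturitions_per_day: [-0.10, 0.50]
      nma_mean_diff.incontinence_per_day: [-0.10, 0.20]
  fesoterodine_4mg:
    monthly_cost: 28.01
    ae_prob_3m: {dry_mouth: 0.151, constipation: 0.037}
    discontinuation_monthly_no_ae: 0.068
    nma_mean_diff: {micturitions_per_day: 0.15, incontinence_per_day: 0.10}
    dsa:
      ae_prob_3m.dry_mouth: [0.122, 0.193]
      ae_prob_3m.constipation: [0.024, 0.058]
      discontinuation_monthly_no_ae: [0.034, 0.102]
      nma_mean_diff.micturitions_per_day: [-0.15, 0.45]
      nma_mean_diff.incontinence_per_day: [-0.05, 0.25]
  fesoterodine_8mg:
    monthly_cost: 28.01
    ae_prob_3m: {dry_mouth: 0.289, constipation: 0.069}
    discontinuation_monthly_no_ae: 0.068
    nma_mean_diff: {micturitions_per_day: 0.25, incontinence_per_day: 0.12}
    dsa:
      ae_prob_3m.dry_mouth: [0.248, 0.337]
      ae_prob_3m.constipation: [0.048, 0.100]
      discontinuation_monthly_no_ae: [0.034, 0.102]
      nma_mean_diff.micturitions_per_day: [-0.05, 0.55]
      nma_mean_diff.incontinence_per_day: [-0.03, 0.27]
  oxybutynin_er_10mg:
    monthly_cost: 27.92
    ae_prob_3m: {dry_mouth: 0.210, constipation: 0.037}
    discontinuation_monthly_no_ae: 0.068
    nma_mean_diff: {micturitions_per_day: 0.10, incontinence_per_day: 0.08}
    dsa:
      ae_prob_3m.dry_mouth: [0.163, 0.272]
      ae_prob_3m.constipation: [0.017, 0.075]
      discontinuation_monthly_no_ae: [0.034, 0.102]
      nma_mean_diff.micturitions_per_day: [-0.20, 0.40]
      nma_mean_diff.incontinence_per_day: [-0.07, 0.23]
  oxybutynin_ir_10mg:
    monthly_cost: 2.40
    ae_prob_3m: {dry_mouth: 0.371, constipation: 0.037}
    discontinuation_monthly_no_ae: 0.068
    nma_mean_diff: {micturitions_per_day: 0.20, incontinence_per_day: 0.10}
    dsa:
      ae_prob_3m.dry_mouth: [0.264, 0.510]
      ae_prob_3m.constipation: [0.021, 0.064]
      discontinuation_monthly_no_ae: [0.034, 0.102]
      nma_mean_diff.micturitions_per_day: [-0.10, 0.50]
      nma_mean_diff.incontinence_per_day: [-0.05, 0.25]
  solifenacin_10mg:
    monthly_cost: 36.41
    ae_prob_3m: {dry_mouth: 0.275, constipation: 0.122}
    discontinuation_monthly_no_ae: 0.068
    nma_mean_diff: {micturitions_per_day: -0.10, incontinence_per_day: -0.05}
    dsa:
      ae_prob_3m.dry_mouth: [0.243, 0.309]
      ae_prob_3m.constipation: [0.099, 0.150]
      discontinuation_monthly_no_ae: [0.034, 0.102]
      nma_mean_diff.micturitions_per_day: [-0.40, 0.20]
      nma_mean_diff.incontinence_per_day: [-0.20, 0.10]
  tolterodine_ir_4mg:
    monthly_cost: 2.88
    ae_prob_3m: {dry_mouth: 0.223, constipation: 0.037}
    discontinuation_monthly_no_ae: 0.068
    nma_mean_diff: {micturitions_per_day: 0.20, incontinence_per_day: 0.05}
    dsa:
      ae_prob_3m.dry_mouth: [0.181, 0.257]
      ae_prob_3m.constipation: [0.017, 0.075]
      discontinuation_monthly_no_ae: [0.034, 0.102]
      nma_mean_diff.micturitions_per_day: [-0.10, 0.50]
      nma_mean_diff.incontinence_per_day: [-0.10, 0.20]
  trospium_60mg:
    monthly_cost: 25.04
    ae_prob_3m: {dry_mouth: 0.127, constipation: 0.151}
    discontinuation_monthly_no_ae: 0.068
    nma_mean_diff: {micturitions_per_day: 0.05, incontinence_per_day: 0.02}
    dsa:
      ae_prob_3m.dry_mouth: [0.077, 0.185]
      ae_prob_3m.constipation: [0.081, 0.277]
      discontinuation_monthly_no_ae: [0.034, 0.102]
      nma_mean_diff.micturitions_per_day: [-0.25, 0.35]
      nma_mean_diff.incontinence_per_day: [-0.13, 0.17]

pathway:
  p_discontinue_ae: 0.90
  p_discontinue_no_ae: 0.068
  p_switch_after_discontinuation: 0.261
  p_restart_monthly: 0.056
  restart_split: {previous: 0.333333333333333, next_line_a: 0.333333333333333, next_line_b: 0.333333333333334}
  p_btxa_monthly: 0.001
  p_btxa_reinjection_6m: 0.70
  next_line_a: tolterodine_er_4mg
  next_line_b: oxybutynin_ir_10mg
  next_line_transition_source: tolterodine_er_4mg
  dsa:
    p_discontinue_ae: [0.50, 1.00]
    p_switch_after_discontinuation: [0.067, 0.391]
    p_restart_monthly: [0.0, 0.0842]
    p_btxa_monthly: [0.0, 0.005]
    p_btxa_reinjection_6m: [0.50, 1.00]

utility:
  base_utility: 0.76
  mict_coefs: [0.0632, 0.0422, 0.0204, 0.0104]
  incont_coefs: [0.0586, 0.0437, 0.0314, 0.0157]
  ae_decrement: -0.0357
  dsa:
    mict_coefs.1: [0.0453, 0.0811]
    mict_coefs.2: [0.0258, 0.0587]
    mict_coefs.3: [0.0045, 0.0363]
    mict_coefs.4: [0.0104, 0.0316]
    incont_coefs.1: [0.0422, 0.0749]
    incont_coefs.2: [0.0271, 0.0602]
    incont_coefs.3: [0.0142, 0.0486]
    incont_coefs.4: [0.0128, 0.0369]
    ae_decrement: [-0.1, 0.0]

cost:
  pads_per_month: [6.97, 23.48, 44.47, 58.13, 121.30]
  pad_unit_cost: 0.17
  gp_first_visit: 65.00
  gp_followup: 27.00
  specialist_visit: 94.00
  specialist_visits_at_initiation: 1
  btxa_injection_cost: 1151.98
  dsa:
    pads_per_month.1: [5.83, 8.10]
    pads_per_month.2: [20.80, 26.16]
    pads_per_month.3: [39.76, 49.18]
    pads_per_month.4: [52.10, 64.15]
    pads_per_month.5: [111.88, 130.72]
    specialist_visits_at_initiation: [0, 2]

settings:
  cycle_length: 1
  horizon: 60
  annual_discount_rate: 0.035
  baseline_distribution: {decay: [0.7, 0.7]}
  severity_midpoints:
    micturition: [6, 9, 11, 13, 16]
    incontinence: [0, 0.5, 1.5, 3, 6]
  wtp_grid: [0, 2000, 4000, 6000, 8000, 10000, 12000, 14000, 16000, 18000,
             20000, 22000, 24000, 26000, 28000, 30000, 32000, 34000, 36000,
             38000, 40000, 42000, 44000, 46000, 48000, 50000]
  seed: 1
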
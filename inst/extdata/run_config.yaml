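# Default pipeline configuration: the study's primary parameters.
cost_structures: default

wage_policy:
  base_rate: 45
  on_cost_multiplier: 1.17
  penalty_loading: 1.5

breakeven:
  max_enrollments: 60
  enrollment_fee: 250
  modes:
    web:
      facilitator_hours: 14
      facilitator_rate: 60
      other_fixed: 750
      variable_per_participant: 8
      class_capacity: 20
      axes:
        facilitator_hours: [8, 32, 40, 48]
        facilitator_rate: [35, 90, 120, 200]
        class_capacity: [10, 30, 40, 50, 60]
        enrollment_fee: [100, 200, 400, 600, 800, 1000]
        all_costs_scale: [2, 3, 4, 0.5]
    face_to_face:
      facilitator_hours: 9
      facilitator_rate: 90
      other_fixed: 2250
      variable_per_participant: 35
      class_capacity: 20
      axes:
        facilitator_hours: [12, 16]
        facilitator_rate: [35, 60, 120, 200]
        class_capacity: [10, 30, 40, 60]
        enrollment_fee: [100, 200, 400, 600, 800, 1000]
        all_costs_scale: [2, 3, 4, 0.5]

cea:
  enrolled: 20
  completers: {face_to_face: 14, web: 13}
  mean_grade: {face_to_face: 0.816, web: 0.832}
  qase_override: {web: 11.63}
  in_work_hours: {face_to_face: 8, web: 9.6}
  enrollment_fee: 250
  alt_fee_factor: 2.1

cba:
  enrollment_fee: 250
  time_hours: {face_to_face: 12, web: 14.4}
  benefit_context: 3

cohort:
  face_to_face:
    n_enrolled: 68
    completion_probability: 0.7206
    grade_mean: 81.6
    grade_sd: 9.5
    wtp_mean: [129.17, 192.26, 199, 314.14]
    wtp_sd: [117.25, 201.46, 260.83, 423.01]
    rho: [0.46, 0.43, 0.53, 0.45]
    wtp_missing: 0.42
    satisfaction_missing: 0.10
  web:
    n_enrolled: 67
    completion_probability: 0.6567
    grade_mean: 83.2
    grade_sd: 9.9
    wtp_mean: [96.33, 165.57, 159.72, 190.94]
    wtp_sd: [56.37, 102.16, 103.61, 131.40]
    rho: [0.46, 0.43, 0.53, 0.45]
    wtp_missing: 0.24
    satisfaction_missing: 0.10
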
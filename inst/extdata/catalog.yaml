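# Exemplar score catalog: parent family-environment (FES) cohesion and
# conflict subscales, the youth blood-pressure measure, and a parent-report
# difficulties-in-emotion-regulation (DERS) attunement exemplar.
#
# missing_codes are the numeric sentinel responses (refuse to answer = 777,
# don't know = 999) recoded to missing before any kernel runs.
missing_codes: [777, 999]
id_columns: [participant_id, session_id]
scores:
  - name: fc_p_fes__cohes_mean
    items:
      [
        fc_p_fes__cohes_001, fc_p_fes__cohes_002, fc_p_fes__cohes_003,
        fc_p_fes__cohes_004, fc_p_fes__cohes_005, fc_p_fes__cohes_006,
        fc_p_fes__cohes_007, fc_p_fes__cohes_008, fc_p_fes__cohes_009,
      ]
    kernel: ss_mean
    max_na: 1
    nm_companion: true
  - name: fc_p_fes__confl_mean
    items:
      [
        fc_p_fes__confl_001, fc_p_fes__confl_002, fc_p_fes__confl_003,
        fc_p_fes__confl_004, fc_p_fes__confl_005, fc_p_fes__confl_006,
        fc_p_fes__confl_007, fc_p_fes__confl_008, fc_p_fes__confl_009,
      ]
    kernel: ss_mean
    max_na: 1
    nm_companion: true
  - name: ph_y_bp__sys_mean
    items: [ph_y_bp__sys_001, ph_y_bp__sys_002, ph_y_bp__sys_003]
    kernel: ss_mean
    max_na: 2
    nm_companion: true
  - name: ph_y_bp__dia_mean
    items: [ph_y_bp__dia_001, ph_y_bp__dia_002, ph_y_bp__dia_003]
    kernel: ss_mean
    max_na: 2
    nm_companion: true
  - name: ph_y_bp__hrate_mean
    items: [ph_y_bp__hrate_001, ph_y_bp__hrate_002, ph_y_bp__hrate_003]
    kernel: ss_mean
    max_na: 2
    nm_companion: true
  - name: mh_p_ders__attun_mean
    items:
      [
        mh_p_ders__attun_001, mh_p_ders__attun_002, mh_p_ders__attun_003,
        mh_p_ders__attun_004, mh_p_ders__attun_005, mh_p_ders__attun_006,
      ]
    kernel: ss_mean
    max_na: 1
    nm_companion: true
groups:
  fc_p_fes: [fc_p_fes__cohes_mean, fc_p_fes__confl_mean]
  ph_y_bp: [ph_y_bp__sys_mean, ph_y_bp__dia_mean, ph_y_bp__hrate_mean]
  mh_p_ders: [mh_p_ders__attun_mean]
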
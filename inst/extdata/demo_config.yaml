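# Demo run configuration: an 8-chip plate with five sample chips across
# three conditions, two calibrator chips and one blank.
seed: 20240617
plate_type: graft-64
layout:
  - {chip_id: huvec_01, condition: HUVEC, role: sample}
  - {chip_id: huvec_02, condition: HUVEC, role: sample}
  - {chip_id: lvctrl_01, condition: LV-Ctrl, role: sample}
  - {chip_id: lvtf_01, condition: LV-TF, role: sample}
  - {chip_id: lvtf_02, condition: LV-TF, role: sample}
  - {chip_id: cal_01, condition: calibrator, role: calibrator}
  - {chip_id: cal_02, condition: calibrator, role: calibrator}
  - {chip_id: blank_01, condition: blank, role: blank}
curves:
  huvec_01: {t0: 5, tp: 15, P: 4.29, a: 3}
  huvec_02: {t0: 5, tp: 15, P: 4.29, a: 3}
  lvctrl_01: {t0: 5, tp: 15, P: 20.14, a: 3}
  lvtf_01: {t0: 5, tp: 15, P: 80.78, a: 3}
  lvtf_02: {t0: 5, tp: 15, P: 80.78, a: 3}
kinetics:
  sigma: 1
calibration:
  cal_activity: 100
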
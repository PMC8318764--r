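{
  "schema": 1,
  "description": "Published worked-example counts and percentages for the thrombolysis END study. Entries with derived=true carry a count back-derived from a printed percentage (the source prints the percentage only). Entries with a non-empty flag are internally inconsistent in the source and are carried as printed, not corrected.",
  "enrollment": {
    "enrolled": 187,
    "incidence_denominator": 196,
    "flag": "enrolled total (187 = 36 + 151) is irreconcilable with the printed incidence denominators (36/196 = 18.36%, 151/196 = 77.04%)"
  },
  "entries": [
    {"id": "det_male", "section": "baseline", "group": "deterioration", "label": "male", "count": 28, "total": 36, "printed_pct": 77.78, "printed_digits": 2, "derived": false, "flag": ""},
    {"id": "det_female", "section": "baseline", "group": "deterioration", "label": "female", "count": 8, "total": 36, "printed_pct": 22.22, "printed_digits": 2, "derived": false, "flag": ""},
    {"id": "ctrl_male", "section": "baseline", "group": "control", "label": "male", "count": 114, "total": 151, "printed_pct": 75.5, "printed_digits": 1, "derived": false, "flag": ""},
    {"id": "ctrl_female", "section": "baseline", "group": "control", "label": "female", "count": 37, "total": 151, "printed_pct": 24.5, "printed_digits": 1, "derived": false, "flag": ""},
    {"id": "end_incidence", "section": "baseline", "group": "all", "label": "END incidence", "count": 36, "total": 196, "printed_pct": 18.36, "printed_digits": 2, "derived": false, "flag": "recomputes to 18.37; printed denominator 196 conflicts with enrolled 187"},
    {"id": "control_share", "section": "baseline", "group": "all", "label": "no END", "count": 151, "total": 196, "printed_pct": 77.04, "printed_digits": 2, "derived": false, "flag": "printed denominator 196 conflicts with enrolled 187"},
    {"id": "det_standard_dose", "section": "dose", "group": "deterioration", "label": "standard dose", "count": 21, "total": 36, "printed_pct": 58.3, "printed_digits": 1, "derived": true, "flag": ""},
    {"id": "det_low_dose", "section": "dose", "group": "deterioration", "label": "low dose", "count": 15, "total": 36, "printed_pct": 41.7, "printed_digits": 1, "derived": true, "flag": ""},
    {"id": "ctrl_standard_dose", "section": "dose", "group": "control", "label": "standard dose", "count": 76, "total": 151, "printed_pct": 50.3, "printed_digits": 1, "derived": true, "flag": ""},
    {"id": "det_anterior", "section": "imaging", "group": "deterioration", "label": "anterior circulation", "count": 21, "total": 36, "printed_pct": 58.3, "printed_digits": 1, "derived": false, "flag": ""},
    {"id": "det_posterior", "section": "imaging", "group": "deterioration", "label": "posterior circulation", "count": 15, "total": 36, "printed_pct": 41.7, "printed_digits": 1, "derived": false, "flag": ""},
    {"id": "ctrl_anterior", "section": "imaging", "group": "control", "label": "anterior circulation", "count": 96, "total": 151, "printed_pct": 63.6, "printed_digits": 1, "derived": false, "flag": ""},
    {"id": "ctrl_posterior", "section": "imaging", "group": "control", "label": "posterior circulation", "count": 55, "total": 151, "printed_pct": 36.4, "printed_digits": 1, "derived": false, "flag": ""},
    {"id": "det_ica", "section": "imaging", "group": "deterioration", "label": "internal carotid artery", "count": 6, "total": 36, "printed_pct": 16.7, "printed_digits": 1, "derived": false, "flag": ""},
    {"id": "ctrl_ica", "section": "imaging", "group": "control", "label": "internal carotid artery", "count": 10, "total": 151, "printed_pct": 6.62, "printed_digits": 2, "derived": false, "flag": ""},
    {"id": "det_mca", "section": "imaging", "group": "deterioration", "label": "middle cerebral artery", "count": 16, "total": 36, "printed_pct": 44.4, "printed_digits": 1, "derived": false, "flag": "artery counts 6 + 16 do not sum to the group size 36 in the source"},
    {"id": "ctrl_mca", "section": "imaging", "group": "control", "label": "middle cerebral artery", "count": 85, "total": 151, "printed_pct": 56.3, "printed_digits": 1, "derived": false, "flag": "artery counts 10 + 85 do not sum to the group size 151 in the source"},
    {"id": "det_occlusion", "section": "imaging", "group": "deterioration", "label": "vessel occlusion", "count": 30, "total": 36, "printed_pct": 83.33, "printed_digits": 2, "derived": false, "flag": ""},
    {"id": "ctrl_occlusion", "section": "imaging", "group": "control", "label": "vessel occlusion", "count": 74, "total": 151, "printed_pct": 49, "printed_digits": 0, "derived": false, "flag": ""},
    {"id": "det_stenosis", "section": "imaging", "group": "deterioration", "label": "vessel stenosis", "count": 6, "total": 36, "printed_pct": 16.67, "printed_digits": 2, "derived": false, "flag": ""},
    {"id": "ctrl_stenosis", "section": "imaging", "group": "control", "label": "vessel stenosis", "count": 55, "total": 151, "printed_pct": 36.4, "printed_digits": 1, "derived": false, "flag": ""}
  ],
  "tables": {
    "occlusion": {
      "a": 30, "b": 6, "c": 74, "d": 77,
      "description": "occlusion of the responsible great vessel (exposure) by END (outcome): a = deterioration & occluded (30), b = deterioration & not occluded (36 - 30), c = control & occluded (74), d = control & not occluded (151 - 74)"
    }
  },
  "logistic_printed": {
    "nihss": {"B": 0.214, "wald": 9.451, "or": 1.301, "ci": [1.023, 1.254], "p": 0.03,
              "flag": "printed CI does not contain the printed OR, and exp(0.214) = 1.239 != 1.301"},
    "occlusion": {"B": 2.364, "wald": 9.364, "or": 12.419, "ci": [2.361, 43.328], "p": 0.002,
                  "flag": "exp(2.364) = 10.63 != 12.419 as printed"}
  },
  "uncounted_percentages": {
    "hypertension": {"deterioration_pct": 71.2, "control_pct": 53.6,
                     "flag": "no integer counts over 36 / 151 reproduce these percentages; no count fixture constructed"}
  }
}
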
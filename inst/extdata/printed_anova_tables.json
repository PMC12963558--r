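{
  "work_performance": {
    "outcome": "perceived impact on work performance (questionnaire composite)",
    "eta_convention": "classical",
    "rows": [
      {"source": "Explainability", "stratum": "within", "ss": 0.006, "ss_ulp": 0.001, "df": 1, "F": 0.255, "p": ".620", "eta2": 0.003},
      {"source": "Explainability x Expertise", "stratum": "within", "ss": 0.007, "ss_ulp": 0.001, "df": 1, "F": 0.337, "p": ".568", "eta2": 0.003},
      {"source": "Residuals (within)", "stratum": "within", "ss": 0.422, "ss_ulp": 0.001, "df": 19, "F": null, "p": null, "eta2": null},
      {"source": "Expertise", "stratum": "between", "ss": 0.791, "ss_ulp": 0.001, "df": 1, "F": 16.030, "p": "< .001", "eta2": 0.366},
      {"source": "Residuals (between)", "stratum": "between", "ss": 0.937, "ss_ulp": 0.001, "df": 19, "F": null, "p": null, "eta2": null}
    ]
  },
  "willingness_to_use": {
    "outcome": "willingness to use (questionnaire composite)",
    "eta_convention": "classical",
    "rows": [
      {"source": "Explainability", "stratum": "within", "ss": 0.240, "ss_ulp": 0.001, "df": 1, "F": 4.453, "p": ".048", "eta2": 0.072},
      {"source": "Explainability x Expertise", "stratum": "within", "ss": 0.035, "ss_ulp": 0.001, "df": 1, "F": 0.657, "p": ".427", "eta2": 0.011},
      {"source": "Residuals (within)", "stratum": "within", "ss": 1.024, "ss_ulp": 0.001, "df": 19, "F": null, "p": null, "eta2": null},
      {"source": "Expertise", "stratum": "between", "ss": 0.836, "ss_ulp": 0.001, "df": 1, "F": 13.210, "p": ".002", "eta2": 0.251},
      {"source": "Residuals (between)", "stratum": "between", "ss": 1.203, "ss_ulp": 0.001, "df": 19, "F": null, "p": null, "eta2": null}
    ]
  },
  "workload": {
    "outcome": "EEG workload neurometric (frontal theta / parietal alpha)",
    "eta_convention": "classical",
    "rows": [
      {"source": "Explainability", "stratum": "within", "ss": 0.313, "ss_ulp": 0.001, "df": 1, "F": 5.221, "p": "0.034", "eta2": 0.016},
      {"source": "Explainability x Expertise", "stratum": "within", "ss": 3.580e-4, "ss_ulp": 1e-7, "df": 1, "F": 0.006, "p": "0.939", "eta2": 1.822e-5, "eta2_ulp": 1e-8},
      {"source": "Residuals (within)", "stratum": "within", "ss": 1.139, "ss_ulp": 0.001, "df": 19, "F": null, "p": null, "eta2": null},
      {"source": "Expertise", "stratum": "between", "ss": 0.544, "ss_ulp": 0.001, "df": 1, "F": 0.586, "p": "0.454", "eta2": 0.028},
      {"source": "Residuals (between)", "stratum": "between", "ss": 17.652, "ss_ulp": 0.001, "df": 19, "F": null, "p": null, "eta2": null}
    ]
  },
  "acceptance": {
    "outcome": "EEG acceptance neurometric (right minus left frontal alpha)",
    "eta_convention": "partial",
    "rows": [
      {"source": "Explainability", "stratum": "within", "ss": 0.138, "ss_ulp": 0.001, "df": 1, "F": 3.696, "p": ".070", "eta2": 0.163},
      {"source": "Explainability x Expertise", "stratum": "within", "ss": 0.025, "ss_ulp": 0.001, "df": 1, "F": 0.675, "p": ".421", "eta2": 0.034},
      {"source": "Residuals (within)", "stratum": "within", "ss": 0.708, "ss_ulp": 0.001, "df": 19, "F": null, "p": null, "eta2": null},
      {"source": "Expertise", "stratum": "between", "ss": 1.798, "ss_ulp": 0.001, "df": 1, "F": 3.116, "p": ".094", "eta2": 0.141},
      {"source": "Residuals (between)", "stratum": "between", "ss": 10.967, "ss_ulp": 0.001, "df": 19, "F": null, "p": null, "eta2": null}
    ]
  }
}
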
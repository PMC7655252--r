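# Example rule configuration for emrqc::load_rule_config().
# Every section is optional; omitted sections fall back to the package
# defaults (16 mandatory rules, 13 coding rules, equal weights, the
# 14-standard star scheme with thresholds 5/7/9/11/14).

weights:
  integrity: 0.5
  coding: 0.5

# mandatory_rules: ordered list; requirement NON_BLANK for scalar fields,
# AT_LEAST_ONE for multi-valued fields.
#
# mandatory_rules:
#   - {item: location, field: location, requirement: NON_BLANK}
#   - {item: tcm_symptom, field: tcm_symptoms, requirement: AT_LEAST_ONE}

# coding_rules: ordered list; codeset must resolve in the registry passed to
# assess_batch()/validate_config(); strict items are noncompliant when the
# code is missing, non-strict items are checked only if present.
#
# coding_rules:
#   - {item: gender_code, field: gender_code, codeset: ws445_gender,
#      source: "WS 445.11-2014", strict: true}

# star_scheme: ordered standards (each a conjunction of rule flags) plus
# cumulative thresholds, one per star level.
#
# star_scheme:
#   thresholds: [5, 7, 9, 11, 14]
#   standards:
#     - {name: patient_name, mandatory: [name]}
#     - {name: tcm_symptom_code_valid,
#        mandatory: [tcm_symptom_code], coding: [disease_code]}
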
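- rule_id: CMP-basic_info-occupation
  action: drop
- rule_id: CMP-disease_history-DHCa1
  action: drop
- rule_id: CMP-disease_history-DHCa2
  action: drop
- rule_id: CMP-disease_history-DHCa_other
  action: drop
- rule_id: CMP-disease_history-DHHtn_medication
  action: drop
- rule_id: CMP-disease_history-DHDm_medication
  action: drop
- rule_id: CMP-disease_history-DHEtc_name
  action: drop
- rule_id: CMP-disease_history-FHCa_other
  action: drop
- rule_id: CMP-lifestyle-DR_B
  action: drop
- rule_id: CMP-lifestyle-DR_C
  action: drop
- rule_id: CMP-lifestyle-DR_D
  action: drop
- rule_id: CMP-lifestyle-SM_B
  action: drop
- rule_id: CMP-lifestyle-SM_C
  action: drop
- rule_id: VLD-RNG-measurements-DBP
  action: drop
- rule_id: VLD-RNG-measurements-sbp_gt_dbp
  action: drop
- rule_id: ACC-BR-03-second_cancer_implies_first
  action: drop
- rule_id: ACC-BR-16-cancer_second_type_recorded
  action: drop
- rule_id: ACC-BR-17-nondrinker_no_status
  action: drop
- rule_id: ACC-BR-18-nonsmoker_no_status
  action: drop
- rule_id: ACC-BR-19-no_cancer_no_type
  action: drop
- rule_id: ACC-BR-20-no_cancer_no_second_type
  action: drop
- rule_id: ACC-BR-21-no_other_disease_no_name
  action: drop
- rule_id: ACC-BR-22-no_family_cancer_no_detail
  action: drop
- rule_id: ACC-BR-23-nondiabetic_no_medication
  action: drop
- rule_id: CMP-basic_info-diagnosis_name
  action: set_severity
  new_severity: W
- rule_id: CMP-measurements-KBN_Donor
  action: set_severity
  new_severity: W
- rule_id: CMP-measurements-measure_date
  action: set_severity
  new_severity: W
- rule_id: CMP-measurements-height
  action: set_severity
  new_severity: W
- rule_id: CMP-measurements-weight
  action: set_severity
  new_severity: W
- rule_id: CMP-measurements-SBP
  action: set_severity
  new_severity: W
- rule_id: CMP-measurements-DBP
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-KBN_Donor
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-total_protein
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-albumin
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-glucose
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-hba1c
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-creatinine
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-bun
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-ast
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-alt
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-total_cholesterol
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-triglyceride
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-hdl_cholesterol
  action: set_severity
  new_severity: W
- rule_id: CMP-lab-hemoglobin
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-KBN_Donor
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-DHCa
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-DHHtn
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-DHDm
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-DHTb
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-DHHep
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-DHCvd
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-DHThy
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-DHRen
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-DHEtc
  action: set_severity
  new_severity: W
- rule_id: CMP-disease_history-FHCa
  action: set_severity
  new_severity: W
- rule_id: CMP-lifestyle-KBN_Donor
  action: set_severity
  new_severity: W
- rule_id: VLD-FMT-lab-total_protein
  action: set_severity
  new_severity: W
- rule_id: VLD-FMT-lab-albumin
  action: set_severity
  new_severity: W
- rule_id: VLD-FMT-lab-hba1c
  action: set_severity
  new_severity: W
- rule_id: VLD-FMT-lab-bun
  action: set_severity
  new_severity: W
- rule_id: VLD-FMT-lab-triglyceride
  action: set_severity
  new_severity: W
- rule_id: UNQ-basic_info-KBN_Donor
  action: set_severity
  new_severity: E
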
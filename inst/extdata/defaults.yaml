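params:
  encounter_period: 12.0
  encounter_aware_determiner: 0.5
  patient_activate_determiner: 0.15
  patient_dispirit_determiner: 0.1
  patient_network_edges: 5.0
  patient_influence_across_prop: 0.5
  patient_influence_become_aware_probability: 0.15
  patient_influence_activation_probability: 0.5
  clinician_network_edges: 4.0
  clinician_influence_across_prop: 0.5
  clinician_influence_become_aware_probability: 0.075
  clinician_influence_activation_probability: 0.3
  clinician_dispirit_probability: 0.05
  shared_knowledge_initial: 25.0
  shared_knowledge_half_life: 130.0
  patient_shared_knowledge_contrib_determiner: 0.13
  clinician_shared_knowledge_contrib_determiner: 0.125
  enhanced_registry_initial_per_patient: 5.0
  enhanced_registry_analysis_period: 12.0
  enhanced_registry_record_per_commons_item: 24.0
  potential_phenotype_response_info_from_sk_unit: 0.05
  phenotype_realization_numeric: 0.5
  patient_response_info_half_life: 71.5
  patient_response_info_increase_numeric: 0.275
  patient_response_info_acceleration_from_sk_unit: 0.025
  maximal_patient_response_info_acceleration_from_sk: 1.0
  selection_efficiency_maximum: 505.0
  evaluation_accuracy_minimum_praxis: 0.1005
  patient_engagement_degree_participating: 0.5
  clinician_engagement_degree_participating: 0.5
condition:
  n_phenotypes: 4.0
  n_treatments: 5.0
  responsiveness_kappa: 0.05
  natural_history_drift: 0.0
  relapse_probability: 0.0555
  relapse_magnitude: 0.15
  variability_sd: 0.01
  best_target: 0.85
  worst_target: 0.25
  improvement_tolerance: 0.08
n_care_centers: 4.0
clinicians_per_center: 5.0
patients_per_clinician: 10.0
horizon_steps: 260.0
steps_per_year: 52.0
pvp_level:
- high
- high
- high
- high
er_level:
- medium
- medium
- medium
- medium
closed_cohort: yes
seed_engagement:
  patient_frac: 0.12
  clinician_frac: 0.3
  patient_level: participating
  clinician_level: owning
  patient_owning_frac: 0.03
initial_iri_max: 0.4
exit_rules:
  enabled: no
  upper: 0.95
  lower: 0.05
  consecutive: 8.0
  annual_exit_probability: 0.0
seed: 1
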
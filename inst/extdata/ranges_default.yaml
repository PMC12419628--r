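encounter_period:
  lower: 11.0
  upper: 13.0
  dist: uniform
encounter_aware_determiner:
  lower: 0.0
  upper: 1.0
  dist: uniform
patient_activate_determiner:
  lower: 0.0
  upper: 0.3
  dist: uniform
patient_dispirit_determiner:
  lower: 0.0
  upper: 0.2
  dist: uniform
patient_network_edges:
  lower: 0.0
  upper: 10.0
  dist: uniform
patient_influence_across_prop:
  lower: 0.0
  upper: 1.0
  dist: uniform
patient_influence_become_aware_probability:
  lower: 0.0
  upper: 0.3
  dist: uniform
patient_influence_activation_probability:
  lower: 0.0
  upper: 1.0
  dist: uniform
clinician_network_edges:
  lower: 1.0
  upper: 7.0
  dist: uniform
clinician_influence_across_prop:
  lower: 0.0
  upper: 1.0
  dist: uniform
clinician_influence_become_aware_probability:
  lower: 0.0
  upper: 0.15
  dist: uniform
clinician_influence_activation_probability:
  lower: 0.0
  upper: 0.6
  dist: uniform
clinician_dispirit_probability:
  lower: 0.0
  upper: 0.1
  dist: uniform
shared_knowledge_initial:
  lower: 0.0
  upper: 50.0
  dist: uniform
shared_knowledge_half_life:
  lower: 52.0
  upper: 208.0
  dist: uniform
patient_shared_knowledge_contrib_determiner:
  lower: 0.08
  upper: 0.18
  dist: uniform
clinician_shared_knowledge_contrib_determiner:
  lower: 0.09
  upper: 0.16
  dist: uniform
enhanced_registry_initial_per_patient:
  lower: 0.0
  upper: 10.0
  dist: uniform
enhanced_registry_analysis_period:
  lower: 6.0
  upper: 18.0
  dist: uniform
enhanced_registry_record_per_commons_item:
  lower: 18.0
  upper: 30.0
  dist: uniform
potential_phenotype_response_info_from_sk_unit:
  lower: 0.0
  upper: 0.1
  dist: uniform
phenotype_realization_numeric:
  lower: 0.0
  upper: 1.0
  dist: uniform
patient_response_info_half_life:
  lower: 13.0
  upper: 130.0
  dist: uniform
patient_response_info_increase_numeric:
  lower: 0.05
  upper: 0.5
  dist: uniform
patient_response_info_acceleration_from_sk_unit:
  lower: 0.0
  upper: 0.05
  dist: uniform
maximal_patient_response_info_acceleration_from_sk:
  lower: 0.0
  upper: 2.0
  dist: uniform
selection_efficiency_maximum:
  lower: 10.0
  upper: 1000.0
  dist: uniform
evaluation_accuracy_minimum_praxis:
  lower: 0.001
  upper: 0.2
  dist: uniform
patient_engagement_degree_participating:
  lower: 0.0
  upper: 1.0
  dist: uniform
clinician_engagement_degree_participating:
  lower: 0.0
  upper: 1.0
  dist: uniform
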
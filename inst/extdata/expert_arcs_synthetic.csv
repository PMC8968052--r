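from,to
clinical_t,clinical_n
clinical_t,neoadjuvant_chemo
clinical_n,neoadjuvant_chemo
clinical_t,rt_dose
tumor_distance,surgery_procedure
clinical_t,pathological_t
neoadjuvant_chemo,pathological_t
rt_dose,pathological_t
interval_rt_surgery,pathological_t
clinical_n,pathological_n
pathological_t,pathological_n
pathological_t,crm
tumor_distance,crm
clinical_t,outcome
clinical_n,outcome
surgery_procedure,outcome
crm,outcome
pathological_t,outcome
pathological_n,outcome
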
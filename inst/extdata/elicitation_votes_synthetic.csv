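from,to,stage,actor,vote
clinical_t,clinical_n,proposed,expert1,TRUE
clinical_t,neoadjuvant_chemo,proposed,expert1,TRUE
clinical_n,neoadjuvant_chemo,proposed,expert1,TRUE
clinical_t,rt_dose,proposed,expert1,TRUE
tumor_distance,surgery_procedure,proposed,expert1,TRUE
clinical_t,pathological_t,proposed,expert1,TRUE
neoadjuvant_chemo,pathological_t,proposed,expert1,TRUE
rt_dose,pathological_t,proposed,expert1,TRUE
interval_rt_surgery,pathological_t,proposed,expert1,TRUE
clinical_n,pathological_n,proposed,expert1,TRUE
pathological_t,pathological_n,proposed,expert1,TRUE
pathological_t,crm,proposed,expert1,TRUE
tumor_distance,crm,proposed,expert1,TRUE
clinical_t,outcome,proposed,expert1,TRUE
clinical_n,outcome,proposed,expert1,TRUE
surgery_procedure,outcome,proposed,expert1,TRUE
crm,outcome,proposed,expert1,TRUE
pathological_t,outcome,proposed,expert1,TRUE
pathological_n,outcome,proposed,expert1,TRUE
age,outcome,proposed,expert1,TRUE
gender,outcome,proposed,expert1,TRUE
overall_treatment_time,outcome,proposed,expert1,TRUE
adjuvant_chemo,outcome,proposed,expert1,TRUE
clinical_t,clinical_n,proposed,expert2,TRUE
clinical_t,neoadjuvant_chemo,proposed,expert2,TRUE
clinical_n,neoadjuvant_chemo,proposed,expert2,TRUE
clinical_t,rt_dose,proposed,expert2,TRUE
tumor_distance,surgery_procedure,proposed,expert2,TRUE
clinical_t,pathological_t,proposed,expert2,TRUE
neoadjuvant_chemo,pathological_t,proposed,expert2,TRUE
rt_dose,pathological_t,proposed,expert2,TRUE
interval_rt_surgery,pathological_t,proposed,expert2,TRUE
clinical_n,pathological_n,proposed,expert2,TRUE
pathological_t,pathological_n,proposed,expert2,TRUE
pathological_t,crm,proposed,expert2,TRUE
tumor_distance,crm,proposed,expert2,TRUE
clinical_t,outcome,proposed,expert2,TRUE
clinical_n,outcome,proposed,expert2,TRUE
surgery_procedure,outcome,proposed,expert2,TRUE
crm,outcome,proposed,expert2,TRUE
pathological_t,outcome,proposed,expert2,TRUE
pathological_n,outcome,proposed,expert2,TRUE
age,outcome,proposed,expert2,TRUE
gender,outcome,proposed,expert2,TRUE
adjuvant_chemo,outcome,proposed,expert2,TRUE
tumor_distance,interval_rt_surgery,proposed,expert2,TRUE
clinical_t,clinical_n,review,reviewer1,TRUE
clinical_t,neoadjuvant_chemo,review,reviewer1,TRUE
clinical_n,neoadjuvant_chemo,review,reviewer1,TRUE
clinical_t,rt_dose,review,reviewer1,TRUE
tumor_distance,surgery_procedure,review,reviewer1,TRUE
clinical_t,pathological_t,review,reviewer1,TRUE
neoadjuvant_chemo,pathological_t,review,reviewer1,TRUE
rt_dose,pathological_t,review,reviewer1,TRUE
interval_rt_surgery,pathological_t,review,reviewer1,TRUE
clinical_n,pathological_n,review,reviewer1,TRUE
pathological_t,pathological_n,review,reviewer1,TRUE
pathological_t,crm,review,reviewer1,TRUE
tumor_distance,crm,review,reviewer1,TRUE
clinical_t,outcome,review,reviewer1,TRUE
clinical_n,outcome,review,reviewer1,TRUE
surgery_procedure,outcome,review,reviewer1,TRUE
crm,outcome,review,reviewer1,TRUE
pathological_t,outcome,review,reviewer1,TRUE
pathological_n,outcome,review,reviewer1,TRUE
age,outcome,review,reviewer1,TRUE
gender,outcome,review,reviewer1,FALSE
adjuvant_chemo,outcome,review,reviewer1,TRUE
clinical_t,clinical_n,review,reviewer2,TRUE
clinical_t,neoadjuvant_chemo,review,reviewer2,TRUE
clinical_n,neoadjuvant_chemo,review,reviewer2,TRUE
clinical_t,rt_dose,review,reviewer2,TRUE
tumor_distance,surgery_procedure,review,reviewer2,TRUE
clinical_t,pathological_t,review,reviewer2,TRUE
neoadjuvant_chemo,pathological_t,review,reviewer2,TRUE
rt_dose,pathological_t,review,reviewer2,TRUE
interval_rt_surgery,pathological_t,review,reviewer2,TRUE
clinical_n,pathological_n,review,reviewer2,TRUE
pathological_t,pathological_n,review,reviewer2,TRUE
pathological_t,crm,review,reviewer2,TRUE
tumor_distance,crm,review,reviewer2,TRUE
clinical_t,outcome,review,reviewer2,TRUE
clinical_n,outcome,review,reviewer2,TRUE
surgery_procedure,outcome,review,reviewer2,TRUE
crm,outcome,review,reviewer2,TRUE
pathological_t,outcome,review,reviewer2,TRUE
pathological_n,outcome,review,reviewer2,TRUE
age,outcome,review,reviewer2,FALSE
gender,outcome,review,reviewer2,TRUE
adjuvant_chemo,outcome,review,reviewer2,TRUE
clinical_t,clinical_n,final,validator,TRUE
clinical_t,neoadjuvant_chemo,final,validator,TRUE
clinical_n,neoadjuvant_chemo,final,validator,TRUE
clinical_t,rt_dose,final,validator,TRUE
tumor_distance,surgery_procedure,final,validator,TRUE
clinical_t,pathological_t,final,validator,TRUE
neoadjuvant_chemo,pathological_t,final,validator,TRUE
rt_dose,pathological_t,final,validator,TRUE
interval_rt_surgery,pathological_t,final,validator,TRUE
clinical_n,pathological_n,final,validator,TRUE
pathological_t,pathological_n,final,validator,TRUE
pathological_t,crm,final,validator,TRUE
tumor_distance,crm,final,validator,TRUE
clinical_t,outcome,final,validator,TRUE
clinical_n,outcome,final,validator,TRUE
surgery_procedure,outcome,final,validator,TRUE
crm,outcome,final,validator,TRUE
pathological_t,outcome,final,validator,TRUE
pathological_n,outcome,final,validator,TRUE
adjuvant_chemo,outcome,final,validator,FALSE
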
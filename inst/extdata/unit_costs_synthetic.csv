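category,unit,unit_cost,source,year
outpatient_epilepsy,contact,223,synthetic illustrative value,2020/21
outpatient_other,contact,186,synthetic illustrative value,2020/21
outpatient_mental_health,contact,241,synthetic illustrative value,2020/21
inpatient_epilepsy,night,663,synthetic illustrative value,2020/21
inpatient_other,night,555,synthetic illustrative value,2020/21
a_and_e,contact,167,synthetic illustrative value,2020/21
ambulance,contact,292,synthetic illustrative value,2020/21
gp,contact,39,synthetic illustrative value,2020/21
community_nurse,contact,54,synthetic illustrative value,2020/21
community_paediatrician,contact,108,synthetic illustrative value,2020/21
camhs,contact,219,synthetic illustrative value,2020/21
clinical_psychologist,contact,145,synthetic illustrative value,2020/21
counselling,contact,52,synthetic illustrative value,2020/21
medication_epilepsy,item,30,synthetic illustrative value,2020/21
medication_other,item,18,synthetic illustrative value,2020/21
medication_mental_health,item,25,synthetic illustrative value,2020/21
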
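patient_id,race,ethnicity,sex,f508del,baseline_age,insurance_private,smoker,smoking_household,secondhand_smoke,primary_road_density,secondary_road_density,deprivation_index,greenspace_fraction,distance_to_center,drive_time_to_center
P00001,White,NonHispanic,female,homozygous,10.5,1,0,0,0,0.0015,0.003,0.33,0.82,60,50
P00002,Black,Hispanic,male,heterozygous,8.2,0,0,0,1,0.0025,0.005,0.41,0.7,30,30
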
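patient_id,age,sex,pulse_rate,respiratory_rate,systolic_bp,mean_arterial_pressure,temperature,spo2,gcs,avpu,platelet_count,leukocyte_count,band_percent,septic_shock,terminal_illness,lower_respiratory_infection,nursing_home_resident,altered_mental_status,oxygen_by_mask,etiology,abscess_multiplicity,treatment,outcome
P1,60,male,106,20,121,94,37.2,98,15,Alert,250,9000,2,false,false,false,false,false,false,hematogenous,solitary,conservative,survived
P2,78,female,121,22,99,72.5,38.6,95,15,Alert,120,15000,4,false,false,false,false,false,false,contiguous,solitary,aspiration,survived
P3,81,male,150,36,65,38,35.1,74,6,Pain,40,22000,11,true,false,true,false,true,true,hematogenous,multiple,operation,died
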
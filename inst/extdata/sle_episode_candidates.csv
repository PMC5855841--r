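patient_id,episode_id,sex,age_text,trigger,free_interval_h,focal_deficit,irritability,decreased_consciousness,seizures,temperature_c,eeg_abnormal,mri_finding,cns_infection_at_onset,alternative_diagnosis,treatment,duration_h
1,1,M,3 yr 11 mo,head_trauma,3,TRUE,FALSE,TRUE,TRUE,38.5,TRUE,hemispheric_edema,FALSE,FALSE,LEV;PHE;MDZ,96
2,2,M,15 yr,head_trauma,24,FALSE,FALSE,TRUE,FALSE,37.4,FALSE,none,FALSE,FALSE,,48
3,3,F,5 yr,head_trauma,4,FALSE,FALSE,TRUE,FALSE,37.5,FALSE,none,FALSE,FALSE,,7
4,4-I,F,3 yr 6 mo,head_trauma,1,FALSE,TRUE,TRUE,FALSE,38.0,FALSE,none,FALSE,FALSE,,3
4,4-II,F,14 yr 5 mo,infection,,TRUE,TRUE,FALSE,FALSE,38.0,FALSE,none,FALSE,FALSE,LEV,36
5,5-I,F,7 yr 4 mo,head_trauma,12,FALSE,TRUE,TRUE,FALSE,38.6,FALSE,none,FALSE,FALSE,risperidone,168
5,5-II,F,10 yr 2 mo,head_trauma,2,FALSE,TRUE,TRUE,FALSE,38.5,FALSE,none,FALSE,FALSE,MDZ,24
6,6,F,3 yr 3 mo,infection,,FALSE,TRUE,TRUE,TRUE,38.9,TRUE,none,FALSE,FALSE,LEV;PHE;MDZ,264
7,7,M,5 yr 8 mo,infection,,TRUE,FALSE,TRUE,TRUE,38.5,TRUE,none,FALSE,FALSE,VPA;LEV;DZP;MDZ,144
X1,X1,M,6 yr,unknown,,TRUE,FALSE,TRUE,FALSE,37.8,FALSE,ischemic_stroke,FALSE,FALSE,,72
X2,X2,F,4 yr,infection,,FALSE,FALSE,FALSE,TRUE,39.2,TRUE,none,TRUE,TRUE,,48
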
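table,characteristic,count,denominator,printed_pct
cohort,male,5118908,5472629,93.5
cohort,diabetes_v21,1211089,5472629,22.1
cohort,any_mh_sa_v21,694706,5472629,12.7
cohort,any_mh_sa_psycms,1958978,5472629,35.8
cohort,ptsd,571654,5472629,10.4
cohort,mood_disorder,1010105,5472629,18.5
cohort,serious_mental_illness,260509,5472629,4.8
cohort,substance_abuse,981144,5472629,17.9
cohort,dementia,41275,5472629,0.8
missed,nicotine_dependence,509926,1266938,40.2
missed,depression_nos,396062,1266938,31.3
missed,ptsd,345338,1266938,27.3
missed,anxiety,129808,1266938,10.2
missed,organic_other,120324,1266938,9.5
missed,alcohol_abuse,73910,1266938,5.8
missed,adjustment_reaction,71128,1266938,5.6
missed,neurotic_depression,63390,1266938,5.0
missed,sexual_dysfunction,59026,1266938,4.7
missed,general_anxiety,44130,1266938,3.5
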
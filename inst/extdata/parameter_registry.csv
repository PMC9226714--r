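# Model input parameter registry: 71 interview-derived parameters, each
# assigned to exactly one of the 12 output aggregates. The membership of the
# Somatic pathologies (24) and Naps (6) aggregates follows the published
# counts; the remaining assignments are by clinical face validity and are
# editable data, not code.
# kind: continuous|ordinal|nominal|binary; scale: native instrument range;
# polarity: always_negative|always_positive|data_dependent.
name,kind,scale_min,scale_max,polarity,aggregate
anxiety_disorder,binary,0,1,always_negative,Anxiety
state_anxiety,continuous,20,80,always_negative,Anxiety
trait_anxiety,continuous,20,80,always_negative,Anxiety
depression_diagnosis,binary,0,1,always_negative,Depression
bdi_severity,continuous,0,63,always_negative,Depression
anhedonia,ordinal,1,5,always_negative,Depression
hopelessness,ordinal,1,5,always_negative,Depression
sleep_inertia_severity,ordinal,1,5,always_negative,Sleep inertia
morning_confusion,ordinal,1,5,always_negative,Sleep inertia
difficulty_awakening,ordinal,1,5,always_negative,Sleep inertia
alarm_dependence,binary,0,1,always_negative,Sleep inertia
post_nap_inertia,ordinal,1,5,always_negative,Sleep inertia
work_impairment,ordinal,1,5,always_negative,Work and social impairment
social_withdrawal,ordinal,1,5,always_negative,Work and social impairment
family_strain,ordinal,1,5,always_negative,Work and social impairment
job_change_due_to_ih,binary,0,1,always_negative,Work and social impairment
education_impact,ordinal,1,5,always_negative,Work and social impairment
driving_restriction,binary,0,1,always_negative,Work and social impairment
income_loss,ordinal,1,5,always_negative,Work and social impairment
leisure_impairment,ordinal,1,5,always_negative,Work and social impairment
ess_score,continuous,0,24,always_negative,Sleepiness
sleep_attacks,ordinal,1,5,always_negative,Sleepiness
drowsy_driving,binary,0,1,always_negative,Sleepiness
sleepiness_at_work,ordinal,1,5,always_negative,Sleepiness
morning_sleepiness,ordinal,1,5,always_negative,Sleepiness
sleep_pressure,ordinal,1,5,always_negative,Sleepiness
fatigue_severity,continuous,9,63,always_negative,Fatigue
physical_exhaustion,ordinal,1,5,always_negative,Fatigue
mental_fatigue,ordinal,1,5,always_negative,Fatigue
exercise_intolerance,ordinal,1,5,always_negative,Fatigue
nap_frequency,continuous,0,14,data_dependent,Naps
nap_duration,continuous,0,300,data_dependent,Naps
nap_refreshing,ordinal,1,5,data_dependent,Naps
planned_naps,binary,0,1,data_dependent,Naps
unplanned_naps,binary,0,1,always_negative,Naps
weekend_catchup_sleep,binary,0,1,data_dependent,Naps
sleep_length_24h,continuous,0,1440,data_dependent,Nocturnal sleep
sleep_quality,ordinal,1,5,data_dependent,Nocturnal sleep
sleep_efficiency,continuous,0,100,data_dependent,Nocturnal sleep
deep_sleep_feeling,ordinal,1,5,data_dependent,Nocturnal sleep
sleep_continuity,ordinal,1,5,data_dependent,Nocturnal sleep
bedtime_regularity,ordinal,1,5,data_dependent,Nocturnal sleep
other_psychiatric_diagnosis,binary,0,1,always_negative,Other psychiatric disorders
substance_abuse,binary,0,1,always_negative,Other psychiatric disorders
adjustment_disorder,binary,0,1,always_negative,Other psychiatric disorders
headaches,binary,0,1,always_negative,Somatic pathologies
vertebrogenous_pain,binary,0,1,always_negative,Somatic pathologies
gastrointestinal,binary,0,1,always_negative,Somatic pathologies
serious_infections,binary,0,1,always_negative,Somatic pathologies
obesity,binary,0,1,always_negative,Somatic pathologies
hypertension,binary,0,1,always_negative,Somatic pathologies
cardiovascular,binary,0,1,always_negative,Somatic pathologies
autoimmune_non_cns,binary,0,1,always_negative,Somatic pathologies
thyreopathy,binary,0,1,always_negative,Somatic pathologies
respiratory,binary,0,1,always_negative,Somatic pathologies
urologic,binary,0,1,always_negative,Somatic pathologies
vegetative_dysfunction,binary,0,1,always_negative,Somatic pathologies
inflammatory_cns,binary,0,1,always_negative,Somatic pathologies
endocrine_disorder,binary,0,1,always_negative,Somatic pathologies
epilepsy,binary,0,1,always_negative,Somatic pathologies
neuroimmunological,binary,0,1,always_negative,Somatic pathologies
malignancy,binary,0,1,always_negative,Somatic pathologies
cognitive_deficit,binary,0,1,always_negative,Somatic pathologies
diabetes,binary,0,1,always_negative,Somatic pathologies
rheumatoid_arthritis,binary,0,1,always_negative,Somatic pathologies
chronic_pain,binary,0,1,always_negative,Somatic pathologies
allergy,binary,0,1,always_negative,Somatic pathologies
dermatologic,binary,0,1,always_negative,Somatic pathologies
anemia,binary,0,1,always_negative,Somatic pathologies
methylphenidate_effect,continuous,0,100,data_dependent,Methylphenidate effect
modafinil_effect,continuous,0,100,data_dependent,Modafinil effect
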
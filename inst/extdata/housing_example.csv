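study_id,domain_id,outcome_name,direction,design,n_intervention,quality
S01,housing_condition,housing_condition_outcome_1,positive,RCT,520,high
S01,housing_condition,housing_condition_outcome_2,positive,RCT,520,high
S01,housing_condition,housing_condition_outcome_3,positive,RCT,520,high
S02,housing_condition,housing_condition_outcome_1,positive,RCT,45,moderate
S03,housing_condition,housing_condition_outcome_1,positive,controlled before-after,120,low
S03,housing_condition,housing_condition_outcome_2,positive,controlled before-after,120,low
S04,housing_condition,housing_condition_outcome_1,positive,cohort,300,high
S04,housing_condition,housing_condition_outcome_2,positive,cohort,300,high
S04,housing_condition,housing_condition_outcome_3,positive,cohort,300,high
S04,housing_condition,housing_condition_outcome_4,positive,cohort,300,high
S04,housing_condition,housing_condition_outcome_5,positive,cohort,300,high
S04,housing_condition,housing_condition_outcome_6,positive,cohort,300,high
S04,housing_condition,housing_condition_outcome_7,positive,cohort,300,high
S04,housing_condition,housing_condition_outcome_8,negative,cohort,300,high
S04,housing_condition,housing_condition_outcome_9,negative,cohort,300,high
S04,housing_condition,housing_condition_outcome_10,negative,cohort,300,high
S05,housing_condition,housing_condition_outcome_1,positive,RCT,301,moderate
S05,housing_condition,housing_condition_outcome_2,positive,RCT,301,moderate
S06,housing_condition,housing_condition_outcome_1,positive,controlled before-after,49,moderate
S07,housing_condition,housing_condition_outcome_1,positive,cohort,50,low
S07,housing_condition,housing_condition_outcome_2,positive,cohort,50,low
S07,housing_condition,housing_condition_outcome_3,positive,cohort,50,low
S07,housing_condition,housing_condition_outcome_4,no_change,cohort,50,low
S08,housing_condition,housing_condition_outcome_1,positive,RCT,,high
S08,housing_condition,housing_condition_outcome_2,positive,RCT,,high
S08,housing_condition,housing_condition_outcome_3,positive,RCT,,high
S08,housing_condition,housing_condition_outcome_4,positive,RCT,,high
S09,housing_condition,housing_condition_outcome_1,positive,controlled before-after,210,moderate
S10,housing_condition,housing_condition_outcome_1,positive,cohort,3000,low
S10,housing_condition,housing_condition_outcome_2,negative,cohort,3000,low
S01,general_health,general_health_outcome_1,positive,RCT,520,high
S01,general_health,general_health_outcome_2,positive,RCT,520,high
S02,general_health,general_health_outcome_1,positive,RCT,45,moderate
S03,general_health,general_health_outcome_1,positive,controlled before-after,120,low
S04,general_health,general_health_outcome_1,positive,cohort,300,high
S04,general_health,general_health_outcome_2,positive,cohort,300,high
S04,general_health,general_health_outcome_3,positive,cohort,300,high
S05,general_health,general_health_outcome_1,positive,RCT,301,moderate
S06,general_health,general_health_outcome_1,negative,controlled before-after,49,moderate
S06,general_health,general_health_outcome_2,negative,controlled before-after,49,moderate
S07,general_health,general_health_outcome_1,positive,cohort,50,low
S07,general_health,general_health_outcome_2,negative,cohort,50,low
S01,respiratory_health,respiratory_health_outcome_1,positive,RCT,520,high
S01,respiratory_health,respiratory_health_outcome_2,positive,RCT,520,high
S01,respiratory_health,respiratory_health_outcome_3,positive,RCT,520,high
S01,respiratory_health,respiratory_health_outcome_4,positive,RCT,520,high
S02,respiratory_health,respiratory_health_outcome_1,positive,RCT,45,moderate
S03,respiratory_health,respiratory_health_outcome_1,positive,controlled before-after,120,low
S03,respiratory_health,respiratory_health_outcome_2,positive,controlled before-after,120,low
S04,respiratory_health,respiratory_health_outcome_1,positive,cohort,300,high
S05,respiratory_health,respiratory_health_outcome_1,positive,RCT,301,moderate
S05,respiratory_health,respiratory_health_outcome_2,positive,RCT,301,moderate
S05,respiratory_health,respiratory_health_outcome_3,positive,RCT,301,moderate
S06,respiratory_health,respiratory_health_outcome_1,negative,controlled before-after,49,moderate
S07,respiratory_health,respiratory_health_outcome_1,positive,cohort,50,low
S07,respiratory_health,respiratory_health_outcome_2,negative,cohort,50,low
S08,respiratory_health,respiratory_health_outcome_1,positive,RCT,,high
S08,respiratory_health,respiratory_health_outcome_2,negative,RCT,,high
S08,respiratory_health,respiratory_health_outcome_3,no_change,RCT,,high
S09,respiratory_health,respiratory_health_outcome_1,positive,controlled before-after,210,moderate
S09,respiratory_health,respiratory_health_outcome_2,positive,controlled before-after,210,moderate
S09,respiratory_health,respiratory_health_outcome_3,negative,controlled before-after,210,moderate
S09,respiratory_health,respiratory_health_outcome_4,negative,controlled before-after,210,moderate
S10,respiratory_health,respiratory_health_outcome_1,negative,cohort,3000,low
S10,respiratory_health,respiratory_health_outcome_2,no_change,cohort,3000,low
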
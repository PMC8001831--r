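patient_id,cohort,age,new_onset_headache,jaw_claudication,aion,crp,wall_thickness,hrtcs_result,final_diagnosis
D001,derivation,62,0,0,none,1,0.5,negative,alternative
D002,derivation,62,0,0,none,1,0.5,negative,alternative
D003,derivation,62,0,0,none,1,0.5,negative,alternative
D004,derivation,62,0,0,none,1,0.5,negative,alternative
D005,derivation,62,0,0,none,1,0.5,negative,alternative
D006,derivation,62,0,0,none,1,0.5,negative,alternative
D007,derivation,62,0,0,none,1,0.5,negative,alternative
D008,derivation,62,0,0,none,1,0.5,negative,alternative
D009,derivation,62,0,0,none,1,0.5,negative,alternative
D010,derivation,62,0,0,none,1,0.5,negative,alternative
D011,derivation,62,0,0,none,1,0.5,negative,alternative
D012,derivation,62,0,0,none,1,0.5,negative,alternative
D013,derivation,62,0,0,none,5,0.5,negative,alternative
D014,derivation,62,0,0,none,5,0.5,negative,alternative
D015,derivation,62,0,0,none,5,0.5,negative,alternative
D016,derivation,62,0,0,none,5,0.5,negative,alternative
D017,derivation,62,0,0,none,5,0.5,negative,alternative
D018,derivation,62,0,0,none,5,0.5,negative,alternative
D019,derivation,62,0,0,none,5,0.5,negative,alternative
D020,derivation,62,0,0,none,5,0.5,negative,alternative
D021,derivation,62,1,0,none,5,0.9,positive,cGCA
D022,derivation,62,1,0,none,5,0.5,negative,cGCA
D023,derivation,62,1,0,none,5,0.5,negative,alternative
D024,derivation,75,0,0,none,5,0.5,negative,alternative
D025,derivation,62,1,0,none,5,0.5,negative,alternative
D026,derivation,75,0,0,none,5,0.5,negative,alternative
D027,derivation,62,1,0,none,5,0.5,negative,alternative
D028,derivation,75,0,0,none,5,0.5,negative,alternative
D029,derivation,62,1,0,none,5,0.5,negative,alternative
D030,derivation,75,0,0,none,5,0.5,negative,alternative
D031,derivation,62,1,0,none,5,0.5,negative,alternative
D032,derivation,75,0,0,none,5,0.5,negative,alternative
D033,derivation,62,1,0,none,5,0.5,negative,alternative
D034,derivation,75,0,0,none,5,0.5,negative,alternative
D035,derivation,62,1,0,none,5,0.5,negative,alternative
D036,derivation,75,0,0,none,5,0.5,negative,alternative
D037,derivation,62,1,0,none,5,0.5,negative,alternative
D038,derivation,62,1,0,none,1,0.9,positive,alternative
D039,derivation,62,1,0,none,1,0.5,negative,alternative
D040,derivation,75,0,0,none,1,0.5,negative,alternative
D041,derivation,62,1,0,none,1,0.5,negative,alternative
D042,derivation,75,0,0,none,1,0.5,negative,alternative
D043,derivation,62,1,0,none,1,0.5,negative,alternative
D044,derivation,75,0,0,none,1,0.5,negative,alternative
D045,derivation,62,1,0,none,1,0.5,negative,alternative
D046,derivation,75,0,0,none,1,0.5,negative,alternative
D047,derivation,62,1,0,none,1,0.5,negative,alternative
D048,derivation,75,0,0,none,1,0.5,negative,alternative
D049,derivation,62,1,0,none,1,0.5,negative,alternative
D050,derivation,75,0,0,none,1,0.5,negative,alternative
D051,derivation,62,1,0,none,1,0.5,negative,alternative
D052,derivation,75,0,0,none,1,0.5,negative,alternative
D053,derivation,62,1,0,none,1,0.5,negative,alternative
D054,derivation,62,1,1,none,5,0.9,positive,cGCA
D055,derivation,62,1,1,none,5,0.9,positive,cGCA
D056,derivation,62,1,1,none,5,0.9,positive,cGCA
D057,derivation,62,1,1,none,5,0.9,positive,cGCA
D058,derivation,62,1,1,none,5,0.5,negative,cGCA
D059,derivation,62,1,1,none,5,0.5,negative,cGCA
D060,derivation,75,1,0,none,1,0.9,positive,alternative
D061,derivation,75,1,0,none,1,0.5,negative,alternative
D062,derivation,75,1,0,none,1,0.5,negative,alternative
D063,derivation,75,1,0,none,1,0.5,negative,alternative
D064,derivation,75,1,0,none,1,0.5,negative,alternative
D065,derivation,75,1,0,none,1,0.5,negative,alternative
D066,derivation,75,1,1,none,5,0.9,positive,cGCA
D067,derivation,75,1,1,none,5,0.9,positive,cGCA
D068,derivation,75,1,1,none,5,0.9,positive,cGCA
D069,derivation,75,1,1,none,5,0.9,positive,cGCA
D070,derivation,75,1,1,none,5,0.5,negative,cGCA
D071,derivation,75,1,0,unilateral,1,0.9,positive,alternative
D072,derivation,75,1,0,unilateral,1,0.5,negative,alternative
D073,derivation,75,1,0,unilateral,1,0.5,negative,alternative
D074,derivation,75,1,0,unilateral,1,0.5,negative,alternative
D075,derivation,75,1,1,unilateral,5,0.9,positive,cGCA
D076,derivation,75,1,1,unilateral,5,0.9,positive,cGCA
D077,derivation,75,1,1,unilateral,5,0.9,positive,cGCA
D078,derivation,75,1,1,unilateral,5,0.9,positive,cGCA
D079,derivation,75,1,1,unilateral,5,0.9,positive,cGCA
D080,derivation,75,1,1,unilateral,5,0.9,positive,cGCA
D081,derivation,75,1,0,bilateral,5,0.9,positive,cGCA
D082,derivation,75,1,0,bilateral,5,0.9,positive,cGCA
D083,derivation,75,1,0,bilateral,5,0.9,positive,cGCA
D084,derivation,75,1,0,bilateral,5,0.9,positive,cGCA
D085,derivation,75,1,0,bilateral,5,0.9,positive,cGCA
D086,derivation,75,1,1,bilateral,5,0.9,positive,cGCA
D087,derivation,75,1,1,bilateral,5,0.9,positive,cGCA
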
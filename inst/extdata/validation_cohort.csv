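patient_id,cohort,age,new_onset_headache,jaw_claudication,aion,crp,wall_thickness,hrtcs_result,final_diagnosis
V001,validation,62,0,0,none,5,0.9,positive,cGCA
V002,validation,62,0,0,none,1,0.9,positive,alternative
V003,validation,62,0,0,none,1,0.5,negative,alternative
V004,validation,62,0,0,none,1,0.5,negative,alternative
V005,validation,62,0,0,none,1,0.5,negative,alternative
V006,validation,62,0,0,none,1,0.5,negative,alternative
V007,validation,62,0,0,none,1,0.5,negative,alternative
V008,validation,62,0,0,none,1,0.5,negative,alternative
V009,validation,62,0,0,none,1,0.5,negative,alternative
V010,validation,62,0,0,none,1,0.5,negative,alternative
V011,validation,62,0,0,none,1,0.5,negative,alternative
V012,validation,62,0,0,none,1,0.5,negative,alternative
V013,validation,62,0,0,none,1,0.5,negative,alternative
V014,validation,62,0,0,none,1,0.5,negative,alternative
V015,validation,62,0,0,none,1,0.5,negative,alternative
V016,validation,62,0,0,none,1,0.5,negative,alternative
V017,validation,62,0,0,none,1,0.5,negative,alternative
V018,validation,62,0,0,none,1,0.5,negative,alternative
V019,validation,62,0,0,none,1,0.5,negative,alternative
V020,validation,62,1,0,none,5,0.5,negative,alternative
V021,validation,75,0,0,none,5,0.5,negative,alternative
V022,validation,62,1,0,none,5,0.5,negative,alternative
V023,validation,62,1,0,none,1,0.9,positive,alternative
V024,validation,75,0,0,none,1,0.9,positive,alternative
V025,validation,62,1,0,none,1,0.9,positive,alternative
V026,validation,75,0,0,none,1,0.9,positive,alternative
V027,validation,62,1,0,none,1,0.9,positive,alternative
V028,validation,75,0,0,none,1,0.9,positive,alternative
V029,validation,62,1,0,none,1,0.9,positive,alternative
V030,validation,62,1,0,none,1,0.5,negative,alternative
V031,validation,75,0,0,none,1,0.5,negative,alternative
V032,validation,62,1,0,none,1,0.5,negative,alternative
V033,validation,75,0,0,none,1,0.5,negative,alternative
V034,validation,62,1,0,none,1,0.5,negative,alternative
V035,validation,75,0,0,none,1,0.5,negative,alternative
V036,validation,62,1,0,none,1,0.5,negative,alternative
V037,validation,75,0,0,none,1,0.5,negative,alternative
V038,validation,62,1,0,none,1,0.5,negative,alternative
V039,validation,75,0,0,none,1,0.5,negative,alternative
V040,validation,62,1,0,none,1,0.5,negative,alternative
V041,validation,75,0,0,none,1,0.5,negative,alternative
V042,validation,62,1,0,none,1,0.5,negative,alternative
V043,validation,75,0,0,none,1,0.5,negative,alternative
V044,validation,62,1,0,none,1,0.5,negative,alternative
V045,validation,75,0,0,none,1,0.5,negative,alternative
V046,validation,62,1,0,none,1,0.5,negative,alternative
V047,validation,75,0,0,none,1,0.5,negative,alternative
V048,validation,62,1,0,none,1,0.5,negative,alternative
V049,validation,75,0,0,none,1,0.5,negative,alternative
V050,validation,62,1,0,none,1,0.5,negative,alternative
V051,validation,75,0,0,none,1,0.5,negative,alternative
V052,validation,62,1,0,none,1,0.5,negative,alternative
V053,validation,75,0,0,none,1,0.5,negative,alternative
V054,validation,62,1,0,none,1,0.5,negative,alternative
V055,validation,75,0,0,none,1,0.5,negative,alternative
V056,validation,62,1,0,none,1,0.5,negative,alternative
V057,validation,75,0,0,none,1,0.5,negative,alternative
V058,validation,62,1,0,none,1,0.5,negative,alternative
V059,validation,75,0,0,none,1,0.5,negative,alternative
V060,validation,62,1,0,none,1,0.5,negative,alternative
V061,validation,62,1,1,none,5,0.9,positive,cGCA
V062,validation,62,1,1,none,5,0.9,positive,cGCA
V063,validation,62,1,1,none,5,0.9,positive,cGCA
V064,validation,62,1,1,none,5,0.9,positive,cGCA
V065,validation,62,1,1,none,5,0.9,positive,cGCA
V066,validation,75,1,0,none,1,0.9,positive,alternative
V067,validation,75,1,0,none,1,0.9,positive,alternative
V068,validation,75,1,0,none,1,0.9,positive,alternative
V069,validation,75,1,0,none,1,0.5,negative,alternative
V070,validation,75,1,0,none,1,0.5,negative,alternative
V071,validation,75,1,0,none,1,0.5,negative,alternative
V072,validation,75,1,0,none,1,0.5,negative,alternative
V073,validation,75,1,0,none,1,0.5,negative,alternative
V074,validation,75,1,0,none,1,0.5,negative,alternative
V075,validation,75,1,0,none,1,0.5,negative,alternative
V076,validation,75,1,0,none,1,0.5,negative,alternative
V077,validation,75,1,0,none,1,0.5,negative,alternative
V078,validation,75,1,0,none,1,0.5,negative,alternative
V079,validation,75,1,0,none,1,0.5,negative,alternative
V080,validation,75,1,0,none,1,0.5,negative,alternative
V081,validation,75,1,0,none,1,0.5,negative,alternative
V082,validation,75,1,0,none,1,0.5,negative,alternative
V083,validation,75,1,0,none,1,0.5,negative,alternative
V084,validation,75,1,0,none,1,0.5,negative,alternative
V085,validation,75,1,0,none,1,0.5,negative,alternative
V086,validation,75,1,0,none,1,0.5,negative,alternative
V087,validation,75,1,0,none,1,0.5,negative,alternative
V088,validation,75,1,1,none,5,0.9,positive,cGCA
V089,validation,75,1,1,none,5,0.9,positive,cGCA
V090,validation,75,1,1,none,5,0.9,positive,cGCA
V091,validation,75,1,1,none,5,0.9,positive,cGCA
V092,validation,75,1,1,none,5,0.9,positive,cGCA
V093,validation,75,1,0,unilateral,1,0.9,positive,alternative
V094,validation,75,1,0,unilateral,1,0.9,positive,alternative
V095,validation,75,1,0,unilateral,1,0.5,negative,alternative
V096,validation,75,1,1,unilateral,5,0.9,positive,cGCA
V097,validation,75,1,1,unilateral,5,0.9,positive,cGCA
V098,validation,75,1,1,unilateral,5,0.9,positive,cGCA
V099,validation,75,1,1,unilateral,5,0.9,positive,cGCA
V100,validation,75,1,1,unilateral,5,0.9,positive,cGCA
V101,validation,75,1,1,unilateral,5,0.9,positive,cGCA
V102,validation,75,1,1,unilateral,5,0.9,positive,cGCA
V103,validation,75,1,1,unilateral,5,0.9,positive,cGCA
V104,validation,75,1,0,bilateral,5,0.9,positive,cGCA
V105,validation,75,1,0,bilateral,5,0.9,positive,cGCA
V106,validation,75,1,0,bilateral,5,0.9,positive,cGCA
V107,validation,75,1,0,bilateral,5,0.9,positive,cGCA
V108,validation,75,1,0,bilateral,5,0.9,positive,cGCA
V109,validation,75,1,0,bilateral,5,0.9,positive,cGCA
V110,validation,75,1,0,bilateral,5,0.9,positive,cGCA
V111,validation,75,1,0,bilateral,5,0.9,positive,cGCA
V112,validation,75,1,1,bilateral,5,0.9,positive,cGCA
V113,validation,75,1,1,bilateral,5,0.9,positive,cGCA
V114,validation,75,1,1,bilateral,5,0.9,positive,cGCA
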
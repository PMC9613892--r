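column	type	class
age	continuous	demographic
sex	categorical	demographic
education_years	ordinal	demographic
moca	ordinal	survey
seadl	ordinal	survey
ess	ordinal	survey
hoehn_yahr	ordinal	physician-exam
sbr_caudate_l	continuous	imaging
sbr_caudate_r	continuous	imaging
sbr_putamen_l	continuous	imaging
sbr_putamen_r	continuous	imaging
updrs1	ordinal	survey
updrs2	ordinal	survey
updrs3	ordinal	physician-exam
updrs_total	continuous	physician-exam
updrs1_1	ordinal	survey
updrs1_2	ordinal	survey
updrs1_3	ordinal	survey
updrs1_4	ordinal	survey
updrs1_5	ordinal	survey
updrs1_6	ordinal	survey
updrs1_7	ordinal	survey
updrs1_8	ordinal	survey
updrs1_9	ordinal	survey
updrs1_10	ordinal	survey
updrs1_11	ordinal	survey
updrs1_12	ordinal	survey
updrs1_13	ordinal	survey
updrs2_1	ordinal	survey
updrs2_2	ordinal	survey
updrs2_3	ordinal	survey
updrs2_4	ordinal	survey
updrs2_5	ordinal	survey
updrs2_6	ordinal	survey
updrs2_7	ordinal	survey
updrs2_8	ordinal	survey
updrs2_9	ordinal	survey
updrs2_10	ordinal	survey
updrs2_11	ordinal	survey
updrs2_12	ordinal	survey
updrs2_13	ordinal	survey
updrs3_1	ordinal	physician-exam
updrs3_2	ordinal	physician-exam
updrs3_3	ordinal	physician-exam
updrs3_4	ordinal	physician-exam
updrs3_5	ordinal	physician-exam
updrs3_6	ordinal	physician-exam
updrs3_7	ordinal	physician-exam
updrs3_8	ordinal	physician-exam
updrs3_9	ordinal	physician-exam
updrs3_10	ordinal	physician-exam
updrs3_11	ordinal	physician-exam
updrs3_12	ordinal	physician-exam
updrs3_13	ordinal	physician-exam
updrs3_14	ordinal	physician-exam
updrs3_15	ordinal	physician-exam
updrs3_16	ordinal	physician-exam
updrs3_17	ordinal	physician-exam
updrs3_18	ordinal	physician-exam
updrs3_19	ordinal	physician-exam
updrs3_20	ordinal	physician-exam
updrs3_21	ordinal	physician-exam
updrs3_22	ordinal	physician-exam
updrs3_23	ordinal	physician-exam
updrs3_24	ordinal	physician-exam
updrs3_25	ordinal	physician-exam
updrs3_26	ordinal	physician-exam
updrs3_27	ordinal	physician-exam
updrs3_28	ordinal	physician-exam
updrs3_29	ordinal	physician-exam
updrs3_30	ordinal	physician-exam
updrs3_31	ordinal	physician-exam
updrs3_32	ordinal	physician-exam
updrs3_33	ordinal	physician-exam
prs_pd	continuous	genetic
prs_ea	continuous	genetic
GBA	categorical	genetic
LRRK2	categorical	genetic
SNCA	categorical	genetic
monogenic_any	categorical	genetic
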
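cohort,leaf,state,feature,interval
WHOLE,1,S0,ADAS13,"(,19.5]"
WHOLE,1,S0,RAVLT_IMMEDIATE,"(,22.5]"
WHOLE,1,S0,AGE,"(,77]"
WHOLE,2,S1,ADAS13,"(,19.5]"
WHOLE,2,S1,RAVLT_IMMEDIATE,"(,22.5]"
WHOLE,2,S1,AGE,"[78,)"
WHOLE,3,S2,ADAS13,"(,19.5]"
WHOLE,3,S2,RAVLT_IMMEDIATE,"(22.5,)"
WHOLE,3,S2,CDRSB,"(,1.8]"
WHOLE,4,S3,ADAS13,"(,19.5]"
WHOLE,4,S3,RAVLT_IMMEDIATE,"(22.5,)"
WHOLE,4,S3,CDRSB,"(1.8,]"
WHOLE,5,S4,ADAS13,"(19.5,25.8]"
WHOLE,5,S4,CDRSB,"(,1.8]"
WHOLE,5,S4,MOCA,"(,19.5]"
WHOLE,6,S5,ADAS13,"(19.5,25.8]"
WHOLE,6,S5,CDRSB,"(1.8,]"
WHOLE,6,S5,MOCA,"(,19.5]"
WHOLE,7,S6,ADAS13,"(19.5,25.8]"
WHOLE,7,S6,MOCA,"(19.5,21.5]"
WHOLE,8,S7,ADAS13,"(19.5,25.8]"
WHOLE,8,S7,MOCA,"(21.5,]"
WHOLE,9,S8,ADAS13,"(25.8,36.2]"
WHOLE,9,S8,CDRSB,"(,1.8]"
WHOLE,9,S8,MOCA,"(,19.5]"
WHOLE,10,S9,ADAS13,"(25.8,36.2]"
WHOLE,10,S9,CDRSB,"(1.8,4.2]"
WHOLE,10,S9,MOCA,"(,19.5]"
WHOLE,11,S10,ADAS13,"(25.8,36.2]"
WHOLE,11,S10,CDRSB,"(4.2,]"
WHOLE,11,S10,MOCA,"(,19.5]"
WHOLE,12,S11,ADAS13,"(36.2,42.7]"
WHOLE,13,S12,ADAS13,"(42.7,)"
AD,1,S13,ADAS13,"(,18.5]"
AD,1,S13,RAVLT_LEARNING,"(,1.5]"
AD,2,S14,ADAS13,"(,18.5]"
AD,2,S14,RAVLT_LEARNING,"(1.5,)"
AD,3,S15,ADAS13,"(18.5,25.2]"
AD,3,S15,MOCA,"(,21.5]"
AD,3,S15,FDG,"(,6]"
AD,4,S16,ADAS13,"(18.5,25.2]"
AD,4,S16,MOCA,"(,21.5]"
AD,4,S16,FDG,"(6,)"
AD,5,S17,ADAS13,"(18.5,25.2]"
AD,5,S17,MOCA,"(21.5,)"
AD,6,S18,ADAS13,"(25.2,35.8)"
AD,6,S18,CDRSB,"(,3.2]"
AD,7,S19,ADAS13,"(25.2,35.8)"
AD,7,S19,CDRSB,"(3.2,)"
AD,7,S19,FDG,"(,5]"
AD,8,S20,ADAS13,"(25.2,35.8)"
AD,8,S20,CDRSB,"(3.2,)"
AD,8,S20,FDG,"(5,)"
AD,9,S21,ADAS13,"(35.8,)"
AD_HTN,1,S22,ADAS13,"(,17.5]"
AD_HTN,1,S22,MOCA,"(,20.5]"
AD_HTN,2,S23,ADAS13,"(17.5,22.2]"
AD_HTN,2,S23,MOCA,"(,20.5]"
AD_HTN,3,S24,ADAS13,"(,22.2]"
AD_HTN,3,S24,MOCA,"(20.5,)"
AD_HTN,4,S25,ADAS13,"(22.2,25.2]"
AD_HTN,4,S25,MOCA,"(,13.5]"
AD_HTN,5,S26,ADAS13,"(22.2,25.2]"
AD_HTN,5,S26,MOCA,"(13.5,)"
AD_HTN,6,S27,ADAS13,"(25.2,31.2]"
AD_HTN,6,S27,CDRSB,"(,1.8]"
AD_HTN,7,S28,ADAS13,"(25.2,31.2]"
AD_HTN,7,S28,CDRSB,"(1.8,3.2]"
AD_HTN,8,S29,ADAS13,"(25.2,31.2]"
AD_HTN,8,S29,CDRSB,"(3.2,)"
AD_HTN,9,S30,ADAS13,"(31.2,41.8]"
AD_HTN,9,S30,AGE,"(,75]"
AD_HTN,10,S31,ADAS13,"(31.2,41.8]"
AD_HTN,10,S31,AGE,"(75,)"
AD_HTN,11,S32,ADAS13,"(41.8,)"
AD_HTN,12,S33,ADAS13,"(25.2,31.2]"
AD_HTN,12,S33,CDRSB,"(,3.2]"
AD_DEP,1,S34,ADAS13,"(,22.2]"
AD_DEP,1,S34,CDRSB,"(,3.75]"
AD_DEP,1,S34,MOCA,"(,20.5]"
AD_DEP,2,S35,ADAS13,"(,22.2]"
AD_DEP,2,S35,CDRSB,"(3.75,)"
AD_DEP,2,S35,MOCA,"(,20.5]"
AD_DEP,3,S36,ADAS13,"(,22.2]"
AD_DEP,3,S36,MOCA,"(20.5,)"
AD_DEP,4,S37,ADAS13,"(22.2,25.2]"
AD_DEP,4,S37,CDRSB,"(,3.75]"
AD_DEP,4,S37,MOCA,"(,21.5]"
AD_DEP,5,S38,ADAS13,"(22.2,25.2]"
AD_DEP,5,S38,CDRSB,"(3.75,)"
AD_DEP,5,S38,MOCA,"(,21.5]"
AD_DEP,6,S39,ADAS13,"(25.2,35.8]"
AD_DEP,6,S39,CDRSB,"(,3.25]"
AD_DEP,7,S40,ADAS13,"(25.2,35.8]"
AD_DEP,7,S40,CDRSB,"(3.25,)"
AD_DEP,8,S41,ADAS13,"(35.8,)"
AD_DEP,8,S41,MOCA,"(,12.5]"
AD_DEP,9,S41,ADAS13,"(35.8,)"
AD_DEP,9,S41,MOCA,"(12.5,)"
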
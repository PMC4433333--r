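patient_id,age,hr_min,hr_max,gcs_min,service,vasopressor,died30,saps
P001,67,58,96,14,MICU,no,0,12
P002,81,64,121,9,MICU,yes,1,21
P003,54,71,104,15,SICU,no,0,9
P004,73,49,88,13,CCU,no,0,14
P005,88,77,139,6,MICU,yes,1,24
P006,45,62,98,15,CSRU,no,0,7
P007,69,55,92,14,CCU,no,0,13
P008,77,83,131,8,SICU,yes,1,19
P009,61,66,101,15,CSRU,no,0,10
P010,70,59,95,12,MICU,no,0,15
P011,83,72,126,7,MICU,yes,0,22
P012,57,68,99,15,SICU,no,0,8
P013,75,52,90,11,CCU,yes,1,18
P014,49,61,97,15,CSRU,no,0,6
P015,66,74,118,10,MICU,no,0,16
P016,79,57,93,13,CCU,no,1,17
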
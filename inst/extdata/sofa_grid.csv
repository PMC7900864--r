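organ,input,op,threshold,score
respiration,pf,lt,400,1
respiration,pf,lt,300,2
respiration,pf,lt,200,3
respiration,pf,lt,100,4
coagulation,platelets,lt,150,1
coagulation,platelets,lt,100,2
coagulation,platelets,lt,50,3
coagulation,platelets,lt,20,4
liver,bilirubin,ge,1.2,1
liver,bilirubin,ge,2,2
liver,bilirubin,ge,6,3
liver,bilirubin,ge,12,4
cardiovascular,map,lt,70,1
cardiovascular,vasopressor,ge,1,2
cns,gcs,lt,15,1
cns,gcs,lt,13,2
cns,gcs,lt,10,3
cns,gcs,lt,6,4
renal,creatinine,ge,1.2,1
renal,creatinine,ge,2,2
renal,creatinine,ge,3.5,3
renal,creatinine,ge,5,4
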
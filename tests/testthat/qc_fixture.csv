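sample_id,gene,replicate,plate_id,ct
S1,ACTB,1,PLA,20
S1,ACTB,2,PLA,20
S1,HPRT,1,PLA,22
S1,HPRT,2,PLA,22
S1,GA,1,PLA,24
S1,GA,2,PLA,24
S1,GB,1,PLA,26
S1,GB,2,PLA,26
S2,ACTB,1,PLA,20
S2,ACTB,2,PLA,20
S2,HPRT,1,PLA,22
S2,HPRT,2,PLA,22
S2,GA,1,PLA,24
S2,GA,2,PLA,Undetermined
S2,GB,1,PLA,26
S2,GB,2,PLA,26
S3,ACTB,1,PLB,20
S3,ACTB,2,PLB,20
S3,HPRT,1,PLB,22
S3,HPRT,2,PLB,22
S3,GA,1,PLB,24
S3,GA,2,PLB,24
S3,GB,1,PLB,Undetermined
S3,GB,2,PLB,Undetermined
S4,ACTB,1,PLB,Undetermined
S4,ACTB,2,PLB,Undetermined
S4,HPRT,1,PLB,22
S4,HPRT,2,PLB,22
S4,GA,1,PLB,24
S4,GA,2,PLB,24
S4,GB,1,PLB,26
S4,GB,2,PLB,26
S5,ACTB,1,PLC,20
S5,ACTB,2,PLC,20
S5,HPRT,1,PLC,28
S5,HPRT,2,PLC,22
S5,GA,1,PLC,24
S5,GA,2,PLC,24
S5,GB,1,PLC,26
S5,GB,2,PLC,26
S6,ACTB,1,PLC,20
S6,ACTB,2,PLC,20
S6,HPRT,1,PLC,22
S6,HPRT,2,PLC,22
S6,GA,1,PLC,30
S6,GA,2,PLC,24
S6,GB,1,PLC,26
S6,GB,2,PLC,26
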
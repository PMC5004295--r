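proteins,model_id,source,note,reference
Cry1Aa1,1CIY,PDB,,published
Cry1Ab16,,UNAVAILABLE,There isn't a deposited model,published
Cry1Ab19,,UNAVAILABLE,There isn't a deposited model,published
Cry1Ac1,4ARX,PDB,,not yet published
Cry1Ac1,4ARY,PDB,,not yet published
Cry1Ac1,4W8J,PDB,,published
Cry1Ld,,UNAVAILABLE,There isn't a deposited model,published
Cry2Aa1,1I5P,PDB,,published
Cry3A,1DLC,PDB,,published
Cry3Aa1,4QX0,PDB,,published
Cry3Aa1,4QX1,PDB,,published
Cry3Aa1,4QX2,PDB,,published
Cry3Bb1,1JI6,PDB,,published
Cry4Aa1,2C9K,PDB,,published
Cry4Ba1,1W99,PDB,,published
Cry4Ba1,4MOA,PDB,,not yet published
Cry5Aa1,PM0074964,PMDB,,published
Cry5B,4D8M,PDB,,published
Cry5Ba1,PM0075036,PMDB,,published
Cry6Aa,5J66,PDB,Pore formation,not yet published
Cry23Aa1;Cry37Aa1,4RHZ,PDB,Binary protein complex,not yet published
Cry8Ea1,3EB7,PDB,,published
Cry11Bb1,,UNAVAILABLE,There isn't a deposited model,published
Cry30Ca2,,UNAVAILABLE,There isn't a deposited model,published
Cry34Ab1,4JOX,PDB,,published
Cry35Ab1,4JP0,PDB,,published
Cry51Aa1,4PKM,PDB,,published
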
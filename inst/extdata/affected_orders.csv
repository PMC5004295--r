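protein,orders
Cry1Aa1,"Diptera, Lepdoptera, Gastropoda"
Cry1Ab16,"Diptera, Lepdoptera, Gastropoda"
Cry1Ab19,"Diptera, Lepdoptera, Gastropoda"
Cry1Ac1,"Diptera, Lepdoptera, Gastropoda"
Cry1Ld,Lepdoptera
Cry2Aa1,"Diptera, Hemiptera, Lepdoptera"
Cry3A,"Coleoptera, Hemiptera, Hymenoptera"
Cry3Aa1,"Coleoptera, Hemiptera, Hymenoptera"
Cry3Bb1,Coleoptera
Cry4Aa1,Diptera
Cry4Ba1,Diptera
Cry5Aa1,"Hymenoptera, Rhabditida"
Cry5B,Rhabditida
Cry5Ba1,Rhabditida
Cry6Aa,Rhabditida
Cry23Aa1,Coleoptera
Cry37Aa1,Coleoptera
Cry8Ea1,Coleoptera
Cry11Bb1,Diptera
Cry30Ca2,Diptera
Cry34Ab1,Coleoptera
Cry35Ab1,Coleoptera
Cry51Aa1,"Coleoptera, Hemiptera"
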
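multiple,drug,category,P0,P1,P2,error
1,dofetilide,2,0,0.033,0.967,0.033
1,bepridil,2,0,0,1,0
1,sotalol,2,0,0.3475,0.6525,0.3475
1,quinidine,2,0,0,1,0
1,cisapride,1,0,1,0,0
1,terfenadine,1,0,0.5455,0.4545,0.4545
1,ondansetron,1,0,1,0,0
1,chlorpromazine,1,0.1575,0.8425,0,0.1575
1,verapamil,0,0.9995,0.0005,0,0.0005
1,ranolazine,0,0.9215,0.0785,0,0.0785
1,mexiletine,0,1,0,0,0
1,diltiazem,0,1,0,0,0
10,dofetilide,2,0.0373,0.0580,0.9047,0.1326
10,bepridil,2,0,0,1,0
10,sotalol,2,0,0.712,0.288,0.712
10,quinidine,2,0,0,1,0
10,cisapride,1,0,0.728,0.272,0.272
10,terfenadine,1,0,1,0,0
10,ondansetron,1,0,1,0,0
10,chlorpromazine,1,0.9945,0.0055,0,0.9945
10,verapamil,0,0.3075,0.6925,0,0.6925
10,ranolazine,0,1,0,0,0
10,mexiletine,0,1,0,0,0
10,diltiazem,0,1,0,0,0
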
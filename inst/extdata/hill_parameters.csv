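drug,current,pIC50,pIC50_lo,pIC50_hi,h,h_lo,h_hi
dofetilide,ICaL,6.5845,-0.7468,7.9108,1.163,0.32,9.622
cisapride,ICaL,2.0331,-0.8172,6.4905,0.4261,0.4063,9.736
bepridil,ICaL,5.5516,5.2752,5.71,0.6486,0.4351,0.9191
verapamil,ICaL,6.6951,6.6029,6.7891,1.097,0.861,1.43
terfenadine,ICaL,6.1547,6.0876,6.2131,0.6601,0.595,0.7367
ranolazine,ICaL,NA,NA,NA,NA,NA,NA
sotalol,ICaL,2.1511,1.7907,2.3628,0.8651,0.5902,1.259
mexiletine,ICaL,4.4175,3.9423,4.6525,1.031,0.6484,1.576
quinidine,ICaL,4.2874,3.8501,4.5293,0.5892,0.4384,0.7362
ondansetron,ICaL,4.6469,4.4138,4.7937,0.7526,0.5478,1.024
diltiazem,ICaL,6.9504,6.7786,7.1267,0.7142,0.5344,1.008
chlorpromazine,ICaL,5.0866,4.9108,5.2128,0.8441,0.6105,1.189
dofetilide,IK1,6.4041,-0.7384,7.8736,0.765,0.2685,9.658
cisapride,IK1,4.5305,-0.7411,6.7042,0.5133,0.2572,9.63
bepridil,IK1,NA,NA,NA,NA,NA,NA
verapamil,IK1,0.4574,-0.8155,5.7514,0.2728,0.2526,9.655
terfenadine,IK1,NA,NA,NA,NA,NA,NA
ranolazine,IK1,NA,NA,NA,NA,NA,NA
sotalol,IK1,2.5157,2.385,2.5955,1.204,0.9066,1.611
mexiletine,IK1,NA,NA,NA,NA,NA,NA
quinidine,IK1,1.4024,-0.7594,5.0793,0.3468,0.2715,9.492
ondansetron,IK1,NA,NA,NA,NA,NA,NA
diltiazem,IK1,NA,NA,NA,NA,NA,NA
chlorpromazine,IK1,5.0329,4.8446,5.1718,0.6878,0.5226,0.8822
dofetilide,IKs,NA,NA,NA,NA,NA,NA
cisapride,IKs,1.0906,-0.767,6.528,0.2921,0.2409,9.67
bepridil,IKs,4.5432,3.4422,4.9682,0.7061,0.3907,1.142
verapamil,IKs,NA,NA,NA,NA,NA,NA
terfenadine,IKs,3.3982,0.0077,5.9477,0.543,0.2777,9.728
ranolazine,IKs,1.4418,-0.624,4.3335,0.5191,0.3292,8.066
sotalol,IKs,2.3745,2.0951,2.507,1.167,0.7741,1.698
mexiletine,IKs,NA,NA,NA,NA,NA,NA
quinidine,IKs,5.3099,5.2008,5.3813,1.363,0.9565,2.122
ondansetron,IKs,3.2443,2.138,3.9253,0.6535,0.3954,1.238
diltiazem,IKs,NA,NA,NA,NA,NA,NA
chlorpromazine,IKs,NA,NA,NA,NA,NA,NA
dofetilide,Ito,7.7254,6.8317,7.9571,0.7712,0.3735,1.147
cisapride,Ito,3.6594,-0.6456,5.6778,0.243,0.1166,0.5656
bepridil,Ito,5.0658,-0.5052,5.3383,3.541,0.4166,9.499
verapamil,Ito,4.8719,1.1464,5.5056,0.8222,0.2414,1.793
terfenadine,Ito,3.6198,-0.0501,5.1184,0.2559,0.1246,0.5777
ranolazine,Ito,NA,NA,NA,NA,NA,NA
sotalol,Ito,1.3651,-0.3529,2.1817,0.6632,0.3213,1.704
mexiletine,Ito,NA,NA,NA,NA,NA,NA
quinidine,Ito,5.4575,5.3999,5.511,1.282,1.049,1.585
ondansetron,Ito,2.9901,-0.8308,4.4636,0.9891,0.4407,9.691
diltiazem,Ito,-0.4506,-0.922,2.6212,0.1696,0.1551,0.364
chlorpromazine,Ito,1.754,-0.6914,4.776,0.3654,0.2318,8.56
dofetilide,INaL,3.1231,-0.754,7.8227,0.2597,0.1543,9.49
cisapride,INaL,NA,NA,NA,NA,NA,NA
bepridil,INaL,5.7414,5.6743,5.8074,1.416,1.133,1.789
verapamil,INaL,5.1532,-0.6313,5.8804,1.031,0.222,9.41
terfenadine,INaL,4.6977,2.6363,5.8293,0.6011,0.269,3.232
ranolazine,INaL,5.1033,4.9859,5.2079,0.945,0.7247,1.256
sotalol,INaL,NA,NA,NA,NA,NA,NA
mexiletine,INaL,5.0478,4.9484,5.1128,1.409,1.041,1.846
quinidine,INaL,5.0261,4.9062,5.1077,1.337,1.034,1.7
ondansetron,INaL,4.7172,4.6073,4.8,1.035,0.8001,1.399
diltiazem,INaL,4.6602,4.5116,4.7776,0.6779,0.5485,0.9082
chlorpromazine,INaL,5.341,5.2543,5.4232,0.9379,0.7797,1.148
dofetilide,INa,6.4196,-0.6142,8.0307,0.892,0.2235,9.497
cisapride,INa,NA,NA,NA,NA,NA,NA
bepridil,INa,5.5333,5.3948,5.6158,1.164,0.8083,1.71
verapamil,INa,NA,NA,NA,NA,NA,NA
terfenadine,INa,5.3185,4.8576,6.0114,1.015,0.6554,9.176
ranolazine,INa,4.1626,3.2696,4.5616,1.425,0.6228,9.116
sotalol,INa,-0.0584,-0.8951,2.4926,0.5089,0.3913,8.449
mexiletine,INa,NA,NA,NA,NA,NA,NA
quinidine,INa,4.909,4.6683,5.0426,1.494,1.004,2.236
ondansetron,INa,4.2391,3.5217,4.6469,1.02,0.5024,8.671
diltiazem,INa,3.9551,3.2876,4.8315,0.7022,0.4484,9.337
chlorpromazine,INa,5.3433,5.221,5.4298,1.995,1.628,3.064
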
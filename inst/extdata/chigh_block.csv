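drug,chigh_nM,x_cmax,ICaL,IK1,IKs,INa,INaL,Ito
dofetilide,6,3,1.2,3.4,0.2,2.5,4.6,27.0
bepridil,3000,90.9,50.7,0.5,16.2,51.7,67.0,2.4
sotalol,2100000,143.0,26.0,38.6,30.6,3.9,11.0,11.4
quinidine,5400,1.7,20.2,5.6,55.5,22.3,31.8,64.2
cisapride,125,48.1,0.7,5.3,1.8,2.4,0.0,13.2
terfenadine,800,200,52.0,0.0,3.3,14.0,12.7,20.6
ondansetron,20000,143.9,47.4,3.0,9.9,25.5,51.6,2.0
chlorpromazine,10500,276.3,55.4,51.1,5.2,84.2,69.2,6.0
verapamil,1000,12.3,85.7,3.9,NA,0.5,12.0,9.9
verapamil,500,6.2,NA,NA,2.4,NA,NA,NA
ranolazine,23000,11.8,2.5,0.3,2.1,17.4,72.3,NA
ranolazine,69000,35.4,NA,NA,NA,NA,NA,26.5
mexiletine,10000,2.4,19.5,0.6,0.0,6.1,51.9,1.0
diltiazem,12500,102.5,97.0,4.6,0.0,17.7,40.6,11.0
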
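drug,risk,category
dofetilide,High,2
bepridil,High,2
sotalol,High,2
quinidine,High,2
cisapride,Intermediate,1
terfenadine,Intermediate,1
ondansetron,Intermediate,1
chlorpromazine,Intermediate,1
verapamil,Low,0
ranolazine,Low,0
mexiletine,Low,0
diltiazem,Low,0
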
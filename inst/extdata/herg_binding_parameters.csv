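drug,log10_Kmax,log10_Kmax_lo,log10_Kmax_hi,log10_EC50n,log10_EC50n_lo,log10_EC50n_hi,log10_ratio,log10_ratio_lo,log10_ratio_hi,n,n_lo,n_hi,log10_Ku,log10_Ku_lo,log10_Ku_hi,Vhalftrap,Vhalftrap_lo,Vhalftrap_hi
dofetilide,1.5453,0.9209,6.8153,2.3357,1.7982,7.5726,-0.7905,-1.0125,-0.6304,1.08,0.9527,1.467,-4.7409,-4.9767,-4.6633,-1,-26.01,-1
bepridil,6.7477,5.4278,7.1407,8.1679,6.803,8.5243,-1.4202,-1.7124,-1.1736,0.9374,0.8227,1.074,-3.7647,-3.8713,-3.671,-61.34,-72.94,-18.36
sotalol,4.9831,0.8193,5.4306,8.5861,4.965,8.9975,-3.6029,-4.5017,-3.1522,0.7513,0.6594,0.955,-1.6527,-2.0183,-0.4512,-51.5,-74.62,-7.756
quinidine,2.4404,1.1871,6.4189,4.731,3.6678,8.7601,-2.2906,-2.7484,-2.0986,0.8488,0.7775,1.028,-2.3869,-2.3649,-1.7435,-61.35,-72.31,-5.445
cisapride,1.0095,0.839,1.6553,1.6265,1.4211,2.2125,-0.6171,-0.9699,-0.4154,0.9615,0.5928,1.372,-3.3808,-3.4836,-3.2553,-167.4,-190.3,-156.5
terfenadine,5.0095,1.2953,6.2265,5.6123,1.8881,6.8917,-0.6028,-0.7791,-0.4311,0.6502,0.5033,0.7918,-4.1086,-4.2938,-4.0023,-81.63,-155,-73.87
ondansetron,5.2355,1.5791,6.3269,7.718,4.341,8.7997,-2.4825,-2.7992,-2.2702,0.891,0.83,1.002,-1.6338,-1.7335,-1.3971,-82.2,-88.69,-77.64
chlorpromazine,5.1984,4.696,6.5012,7.6386,7.0863,8.9725,-2.4402,-2.7268,-2.2162,0.8871,0.8006,0.9916,-1.3306,-1.7312,-0.7396,-14.45,-66.29,-2.865
verapamil,6.2289,1.5379,6.803,8.5258,4.1385,8.9922,-2.2969,-2.9551,-1.7767,1.043,0.832,1.317,-3.088,-3.1708,-2.6366,-97.08,-192,-85.3
ranolazine,1.723,1.3627,5.6536,5.1553,4.8122,8.7298,-3.4324,-4.0139,-2.9363,0.9532,0.8248,1.106,-1.6914,-1.914,-0.0004,-94.99,-176.4,-81.16
mexiletine,1.1761,1.0208,1.497,5.8591,5.3159,6.5914,-4.683,-5.5154,-3.9582,1.139,0.956,1.34,-1.1479,-1.4011,-0.016,-87.51,-164.8,-77.68
diltiazem,5.2613,1.6549,5.6663,8.8246,5.7087,8.9997,-3.5634,-4.1562,-3.223,0.9382,0.8612,1.086,-0.5498,-1.0751,0,-90.65,-180.3,-81.18
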
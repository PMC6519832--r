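parameter,mean,se_pct,bsv,bsv_se_pct,fixed
V1,8.83,12,0.315,56.2,FALSE
V2,3.47,10.5,0.11,342,FALSE
CL,4.57,4.5,0.123,50.6,FALSE
CLD,1.75,4.1,0.0336,170,FALSE
Tlag,0.0189,55.1,0.18,200,FALSE
Kdiss0,0.0683,15.1,0.161,124,FALSE
Tchange50,6.15,11.3,0.285,51.4,FALSE
Dissmax,7.86,16.1,0.256,67.2,FALSE
Hill,10,NA,0,NA,TRUE
Ka_trans,2.63,7.6,0.267,51.8,FALSE
Ka,2.68,10,0.189,54.1,FALSE
Frel_IR,1,NA,0.0234,348,TRUE
Frel_GR,1.19,8.5,0.0404,187,FALSE
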
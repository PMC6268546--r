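compound,role,R_pct,R_pct_sd,below_detection_R,perm_pct,perm_pct_sd,logPe,logPe_sd
FA-21-MP,ester,34.1,3.5,FALSE,23.1,1.4,-4.64,0.17
FA-21-EP,ester,45.8,4.1,FALSE,22.2,1.6,-4.52,0.19
FA-21-PhP,ester,71.9,2.8,FALSE,1.3,0.6,-5.68,0.15
FA-21-MB,ester,47.2,3.4,FALSE,18.0,1.3,-4.65,0.12
FA-21-EB,ester,72.8,2.6,FALSE,7.2,0.9,-4.82,0.10
DEX-21-MP,ester,NA,NA,TRUE,23.8,1.5,-4.88,0.17
DEX-21-EP,ester,NA,NA,TRUE,31.6,0.6,-4.70,0.11
DEX-21-PhP,ester,86.5,4.2,FALSE,4.1,1.1,-4.74,0.13
DEX-21-MB,ester,NA,NA,TRUE,37.4,1.5,-4.58,0.15
DEX-21-EB,ester,11.3,3.5,FALSE,33.4,1.2,-4.58,0.13
TA-21-MP,ester,13.5,4.1,FALSE,38.1,1.6,-4.45,0.16
TA-21-EP,ester,32.4,1.7,FALSE,23.0,1.8,-4.66,0.15
TA-21-PhP,ester,51.1,3.8,FALSE,27.1,1.4,-4.07,0.14
TA-21-MB,ester,39.3,4.1,FALSE,16.9,2.0,-4.85,0.23
TA-21-EB,ester,70.1,3.4,FALSE,7.3,1.6,-4.87,0.21
H-21-MP,ester,2.6,1.9,FALSE,14.9,1.8,-5.11,0.25
H-21-EP,ester,17.2,2.2,FALSE,16.3,1.9,-4.99,0.19
H-21-PhP,ester,72.2,3.1,FALSE,10.6,1.2,-4.58,0.15
H-21-MB,ester,9.6,3.2,FALSE,18.5,1.9,-4.97,0.28
H-21-EB,ester,38.6,1.8,FALSE,17.6,1.4,-4.77,0.17
FA,standard,NA,NA,TRUE,6.7,1.2,-5.26,0.15
DEX,standard,4.2,2.0,FALSE,1.3,0.8,-5.99,0.10
TA,standard,4.7,2.3,FALSE,10.8,1.5,-5.01,0.17
H,standard,1.5,0.9,FALSE,0.8,0.5,-6.23,0.09
H-21-Ac,standard,NA,NA,TRUE,10.0,1.7,-5.07,0.19
MF,standard,81.0,2.9,FALSE,7.7,1.5,-4.10,0.15
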
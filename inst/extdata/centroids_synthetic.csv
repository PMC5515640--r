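phenotype,parameter,mu,sigma
SL,CDT,-2.2,1.3
SL,WDT,-2.0,1.2
SL,TSL,-2.1,1.3
SL,PHS,0.5,0.9
SL,CPT,-0.6,1.2
SL,HPT,-1.1,1.1
SL,MPT,-1.0,1.4
SL,MPS,-0.7,1.2
SL,DMA,0.1,0.5
SL,PPT,-0.5,1.1
SL,WUR,0.2,1.0
SL,MDT,-1.9,1.5
SL,VDT,-1.6,1.4
TH,CDT,-0.3,0.9
TH,WDT,-0.5,1.0
TH,TSL,-0.4,0.9
TH,PHS,0.05,0.3
TH,CPT,0.9,1.3
TH,HPT,0.8,1.1
TH,MPT,0.1,1.1
TH,MPS,0.3,1.0
TH,DMA,0.2,0.6
TH,PPT,0.4,1.1
TH,WUR,0.2,1.0
TH,MDT,-0.3,1.0
TH,VDT,-0.3,0.9
MH,CDT,-1.5,1.3
MH,WDT,-1.3,1.2
MH,TSL,-1.4,1.3
MH,PHS,0.3,0.7
MH,CPT,-0.1,1.1
MH,HPT,-0.3,1.1
MH,MPT,1.2,1.3
MH,MPS,1.4,1.2
MH,DMA,1.1,1.2
MH,PPT,0.5,1.1
MH,WUR,0.8,1.2
MH,MDT,-0.9,1.3
MH,VDT,-0.7,1.2
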
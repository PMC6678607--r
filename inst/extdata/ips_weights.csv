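gene,category,weight
HLA-A,MHC,1
HLA-B,MHC,1
HLA-C,MHC,1
HLA-DPA1,MHC,1
HLA-DPB1,MHC,1
HLA-E,MHC,1
HLA-F,MHC,1
TAP1,MHC,1
TAP2,MHC,1
B2M,MHC,1
CD274,immunomodulator,-0.5
CTLA4,immunomodulator,-0.5
PDCD1,immunomodulator,-0.5
LAG3,immunomodulator,-0.5
TIGIT,immunomodulator,-0.5
CD27,immunomodulator,1
ICOS,immunomodulator,1
CD40,immunomodulator,1
TNFRSF9,immunomodulator,1
CD8A,effector,1
GZMA,effector,1
GZMB,effector,1
PRF1,effector,1
IFNG,effector,1
NKG7,effector,1
GZMK,effector,1
FOXP3,suppressor,-1
IL10,suppressor,-1
TGFB1,suppressor,-1
CCL22,suppressor,-1
IDO2,suppressor,-1
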
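proxy,F1,F2
HR,-0.494,0.559
RR_RMS,0.867,-0.405
RR_TP,0.840,-0.290
RR_LFa,0.681,0.031
RR_HFa,0.654,-0.275
RR_LFnu,-0.185,0.707
RR_HFnu,0.340,-0.708
RMSSD,0.854,-0.380
AC,-0.760,0.231
DC,0.752,-0.068
RR_Ro,-0.229,0.915
P0v,0.014,0.904
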
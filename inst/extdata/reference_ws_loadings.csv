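proxy,F1,F2,F3
HR,-0.810,0.149,-0.105
RR_RMS,0.857,0.189,0.005
RR_TP,0.854,-0.107,-0.248
RR_LFa,0.723,-0.034,0.131
RR_HFa,0.603,-0.156,-0.442
RR_LFnu,0.355,0.091,0.782
RR_HFnu,0.199,-0.027,-0.761
RMSSD,0.914,-0.257,-0.123
AC,-0.856,0.271,-0.011
DC,0.829,-0.203,0.022
RR_Ro,-0.153,0.953,0.041
P0v,-0.150,0.962,0.110
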
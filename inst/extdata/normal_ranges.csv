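metric,lower,upper
EDV,102,202
ESV,24,92
SV,57,150
LVEF,50,65
CO,4,8
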
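id,EDV_chg,ESV_chg,SV_chg,LVEF_chg,CO_chg
S01,3.05,21.30,-12.31,-14.90,-12.30
S02,1.61,10.06,-5.51,-7.00,-5.50
S03,-1.99,-8.67,3.63,5.74,3.63
S04,-4.48,-15.76,5.02,9.94,5.03
S11,-39.89,-22.23,-54.76,-24.73,-54.75
S12,-17.56,-16.47,-18.47,-1.11,-18.47
S13,0.64,9.70,-6.99,-7.58,-6.99
S14,1.31,20.11,-14.52,-15.62,-14.51
S21,-36.02,-4.30,-62.70,-41.71,-62.70
S22,-21.56,-6.82,-33.96,-15.81,-33.96
S23,-1.43,-0.19,-2.48,-1.06,-2.47
S24,-3.48,-0.35,-6.11,-2.73,-6.10
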
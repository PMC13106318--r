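id,EDV_mL,ESV_mL,SV_mL,LVEF_pct,CO_Lmin
S00,142.789,65.248,77.541,54.305,4.652
S01,147.147,79.149,67.998,46.211,4.080
S02,145.086,71.815,73.271,50.502,4.396
S03,139.946,59.589,80.357,57.420,4.821
S04,136.392,54.962,81.430,59.703,4.886
S11,85.827,50.745,35.082,40.875,2.105
S12,117.718,54.500,63.218,53.703,3.793
S13,143.697,71.574,72.123,50.191,4.327
S14,144.654,78.371,66.283,45.822,3.977
S21,91.362,62.443,28.919,31.653,1.735
S22,112.003,60.796,51.207,45.719,3.072
S23,140.746,65.127,75.619,53.727,4.537
S24,137.821,65.020,72.801,52.823,4.368
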
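# Default parameter sets. Units: stresses MPa, lengths um at the interface
# (B and m act on mm internally), times s, volumes mL, pressures mmHg.

[passive]            # orthotropic hyperelastic law, verification values
a = 0.004            # MPa
b = 8.0
a_f = 0.005          # MPa
b_f = 5.0
a_s = 0.002          # MPa
b_s = 2.0
a_fs = 0             # MPa; no published verification value, axis-aligned cases unaffected
b_fs = 1.0
D = 0.001            # 1/MPa, volumetric compliance (compressible mode only)

[active]             # time-varying elastance law, default set
T_max = 0.1          # MPa
Ca0 = 4.35
Ca0_max = 4.35
B = 4750             # 1/mm
t0 = 0.1             # s
m = 1048.9           # s/mm
b_relax = -1.429     # s
L_r = 1.85           # um
L_0 = 1.58           # um

[surrogate]          # frozen calibration of the 0D closed-loop left heart
V_wall = 140         # mL
V_ref = 100          # mL
E_la = 0.18          # mmHg/mL
V_la0 = 5            # mL
C_art = 1.3          # mL/mmHg
V_art0 = 350         # mL
C_ven = 60           # mL/mmHg
V_ven0 = 900         # mL
R_mit = 0.025        # mmHg s/mL
R_ao = 0.012         # mmHg s/mL
R_p = 1.05           # mmHg s/mL
R_ven = 0.035        # mmHg s/mL
total_volume = 2400  # mL
cycle_length = 1.0   # s
beat_duration = 0.5  # s
preload_time = 0.3   # s
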
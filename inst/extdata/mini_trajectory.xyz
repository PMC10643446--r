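2
time_fs=0.0 E0_eV=0.0 E1_eV=4.0 state=1 seed=7
C  0.0000000000 0.0000000000 0.0000000000
O  1.2200000000 0.0000000000 0.0000000000
2
time_fs=0.5 E0_eV=0.0 E1_eV=3.5 state=1
C  0.0000000000 0.0000000000 0.0000000000
O  1.2500000000 0.0000000000 0.0000000000
2
time_fs=1.0 E0_eV=0.0 E1_eV=0.05 state=0
C  0.0000000000 0.0000000000 0.0000000000
O  1.3100000000 0.0000000000 0.0000000000
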
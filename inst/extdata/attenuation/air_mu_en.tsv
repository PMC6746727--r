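energy_keV	mu_en_over_rho_cm2_g
10.0000	4.742000e+00
15.0000	1.334000e+00
20.0000	5.389000e-01
30.0000	1.537000e-01
40.0000	6.833000e-02
50.0000	4.098000e-02
60.0000	3.041000e-02
80.0000	2.407000e-02
100.0000	2.325000e-02
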
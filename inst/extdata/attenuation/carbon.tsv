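energy_keV	mu_over_rho_cm2_g
15.0000	8.0015496372e-01
15.2500	7.7052799765e-01
15.5000	7.4280991676e-01
15.7500	7.1684759828e-01
16.0000	6.9250244683e-01
16.2500	6.6964882024e-01
16.5000	6.4817263038e-01
16.7500	6.2797014198e-01
17.0000	6.0894687637e-01
17.2500	5.9101667629e-01
17.5000	5.7410085360e-01
17.7500	5.5812745273e-01
18.0000	5.4303058398e-01
18.2500	5.2874983367e-01
18.5000	5.1522974514e-01
18.7500	5.0241934574e-01
19.0000	4.9027172932e-01
19.2500	4.7874368477e-01
19.5000	4.6779535519e-01
19.7500	4.5738994333e-01
20.0000	4.4749343511e-01
20.2500	4.3807435858e-01
20.5000	4.2910356361e-01
20.7500	4.2055402484e-01
21.0000	4.1240065991e-01
21.2500	4.0462017078e-01
21.5000	3.9719089469e-01
21.7500	3.9009267275e-01
22.0000	3.8330672533e-01
22.2500	3.7681554726e-01
22.5000	3.7060280546e-01
22.7500	3.6465324652e-01
23.0000	3.5895261580e-01
23.2500	3.5348758343e-01
23.5000	3.4824566807e-01
23.7500	3.4321518144e-01
24.0000	3.3838516589e-01
24.2500	3.3374534310e-01
24.5000	3.2928606314e-01
24.7500	3.2499826157e-01
25.0000	3.2087341942e-01
25.2500	3.1690352223e-01
25.5000	3.1308102536e-01
25.7500	3.0939882570e-01
26.0000	3.0585022849e-01
26.2500	3.0242892136e-01
26.5000	2.9912894708e-01
26.7500	2.9593884647e-01
27.0000	2.9283730247e-01
27.2500	2.8984350853e-01
27.5000	2.8695254352e-01
27.7500	2.8415975287e-01
28.0000	2.8146073602e-01
28.2500	2.7885132887e-01
28.5000	2.7632758759e-01
28.7500	2.7388577783e-01
29.0000	2.7152236006e-01
29.2500	2.6923397757e-01
29.5000	2.6701744692e-01
29.7500	2.6486974648e-01
30.0000	2.6278800687e-01
30.2500	2.6076950332e-01
30.5000	2.5881164567e-01
30.7500	2.5691197151e-01
31.0000	2.5506813860e-01
31.2500	2.5327791828e-01
31.5000	2.5153918911e-01
31.7500	2.4984993050e-01
32.0000	2.4820821759e-01
32.2500	2.4661221592e-01
32.5000	2.4506017709e-01
32.7500	2.4355043057e-01
33.0000	2.4208138671e-01
33.2500	2.4065152507e-01
33.5000	2.3925939419e-01
33.7500	2.3790360865e-01
34.0000	2.3658284412e-01
34.2500	2.3529583476e-01
34.5000	2.3404136995e-01
34.7500	2.3281829122e-01
35.0000	2.3162549121e-01
35.2500	2.3046190924e-01
35.5000	2.2932652996e-01
35.7500	2.2821838058e-01
36.0000	2.2713652961e-01
36.2500	2.2608008377e-01
36.5000	2.2504818673e-01
36.7500	2.2404001802e-01
37.0000	2.2305478937e-01
37.2500	2.2209174519e-01
37.5000	2.2115016052e-01
37.7500	2.2022933840e-01
38.0000	2.1932861051e-01
38.2500	2.1844733379e-01
38.5000	2.1758489107e-01
38.7500	2.1674068847e-01
39.0000	2.1591415546e-01
39.2500	2.1510474373e-01
39.5000	2.1431192516e-01
39.7500	2.1353519142e-01
40.0000	2.1277405452e-01
40.2500	2.1202804310e-01
40.5000	2.1129670369e-01
40.7500	2.1057960072e-01
41.0000	2.0987631333e-01
41.2500	2.0918643619e-01
41.5000	2.0850957847e-01
41.7500	2.0784536372e-01
42.0000	2.0719342895e-01
42.2500	2.0655342359e-01
42.5000	2.0592500964e-01
42.7500	2.0530786151e-01
43.0000	2.0470166372e-01
43.2500	2.0410611325e-01
43.5000	2.0352091564e-01
43.7500	2.0294578851e-01
44.0000	2.0238045715e-01
44.2500	2.0182465737e-01
44.5000	2.0127813359e-01
44.7500	2.0074063862e-01
45.0000	2.0021193368e-01
45.2500	1.9969178720e-01
45.5000	1.9917997580e-01
45.7500	1.9867628395e-01
46.0000	1.9818050098e-01
46.2500	1.9769242548e-01
46.5000	1.9721186204e-01
46.7500	1.9673861969e-01
47.0000	1.9627251498e-01
47.2500	1.9581337006e-01
47.5000	1.9536101234e-01
47.7500	1.9491527510e-01
48.0000	1.9447599625e-01
48.2500	1.9404301885e-01
48.5000	1.9361619117e-01
48.7500	1.9319536530e-01
49.0000	1.9278039836e-01
49.2500	1.9237115147e-01
49.5000	1.9196749038e-01
49.7500	1.9156928439e-01
50.0000	1.9117640684e-01
50.2500	1.9078873503e-01
50.5000	1.9040614912e-01
50.7500	1.9002853353e-01
51.0000	1.8965577505e-01
51.2500	1.8928776582e-01
51.5000	1.8892439817e-01
51.7500	1.8856556994e-01
52.0000	1.8821118060e-01
52.2500	1.8786113281e-01
52.5000	1.8751533177e-01
52.7500	1.8717368545e-01
53.0000	1.8683610471e-01
53.2500	1.8650250209e-01
53.5000	1.8617279326e-01
53.7500	1.8584689609e-01
54.0000	1.8552473004e-01
54.2500	1.8520621755e-01
54.5000	1.8489128264e-01
54.7500	1.8457985183e-01
55.0000	1.8427185293e-01
55.2500	1.8396721646e-01
55.5000	1.8366587373e-01
55.7500	1.8336775901e-01
56.0000	1.8307280768e-01
56.2500	1.8278095648e-01
56.5000	1.8249214452e-01
56.7500	1.8220631194e-01
57.0000	1.8192340064e-01
57.2500	1.8164335366e-01
57.5000	1.8136611618e-01
57.7500	1.8109163426e-01
58.0000	1.8081985525e-01
58.2500	1.8055072807e-01
58.5000	1.8028420218e-01
58.7500	1.8002022986e-01
59.0000	1.7975876296e-01
59.2500	1.7949975534e-01
59.5000	1.7924316166e-01
59.7500	1.7898893793e-01
60.0000	1.7873704091e-01
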
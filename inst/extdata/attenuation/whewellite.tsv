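energy_keV	mu_over_rho_cm2_g
15.0000	9.2034550146e+00
15.2500	8.7835243134e+00
15.5000	8.3892449603e+00
15.7500	8.0186853015e+00
16.0000	7.6700859292e+00
16.2500	7.3418420034e+00
16.5000	7.0324875980e+00
16.7500	6.7406818848e+00
17.0000	6.4651968020e+00
17.2500	6.2049061435e+00
17.5000	5.9587717486e+00
17.7500	5.7251147164e+00
18.0000	5.5039095759e+00
18.2500	5.2943363334e+00
18.5000	5.0956390572e+00
18.7500	4.9071201003e+00
19.0000	4.7281349138e+00
19.2500	4.5580873886e+00
19.5000	4.3964256541e+00
19.7500	4.2426382887e+00
20.0000	4.0962515479e+00
20.2500	3.9568246716e+00
20.5000	3.8239478028e+00
20.7500	3.6972402139e+00
21.0000	3.5763474623e+00
21.2500	3.4609392917e+00
21.5000	3.3507077212e+00
21.7500	3.2453653183e+00
22.0000	3.1446436104e+00
22.2500	3.0482916326e+00
22.5000	2.9560746248e+00
22.7500	2.8677728055e+00
23.0000	2.7831802790e+00
23.2500	2.7021040160e+00
23.5000	2.6243629225e+00
23.7500	2.5497869931e+00
24.0000	2.4782165205e+00
24.2500	2.4095013772e+00
24.5000	2.3435003479e+00
24.7500	2.2800805221e+00
25.0000	2.2191167264e+00
25.2500	2.1604910041e+00
25.5000	2.1040921327e+00
25.7500	2.0498151837e+00
26.0000	1.9975611071e+00
26.2500	1.9472363491e+00
26.5000	1.8987525032e+00
26.7500	1.8519116450e+00
27.0000	1.8063195442e+00
27.2500	1.7623748515e+00
27.5000	1.7200035935e+00
27.7500	1.6791357514e+00
28.0000	1.6397050102e+00
28.2500	1.6016485335e+00
28.5000	1.5649067561e+00
28.7500	1.5294231815e+00
29.0000	1.4951442037e+00
29.2500	1.4620189339e+00
29.5000	1.4299990417e+00
29.7500	1.3990386047e+00
30.0000	1.3690939734e+00
30.2500	1.3401236367e+00
30.5000	1.3120881047e+00
30.7500	1.2849497908e+00
31.0000	1.2586729091e+00
31.2500	1.2332233717e+00
31.5000	1.2085686990e+00
31.7500	1.1846779257e+00
32.0000	1.1615215284e+00
32.2500	1.1390713380e+00
32.5000	1.1173004761e+00
32.7500	1.0961832750e+00
33.0000	1.0756952331e+00
33.2500	1.0558129366e+00
33.5000	1.0365140081e+00
33.7500	1.0177770602e+00
34.0000	9.9958163621e-01
34.2500	9.8190816800e-01
34.5000	9.6473792792e-01
34.7500	9.4805299231e-01
35.0000	9.3183619729e-01
35.2500	9.1607110052e-01
35.5000	9.0074195118e-01
35.7500	8.8583365030e-01
36.0000	8.7133172523e-01
36.2500	8.5722229251e-01
36.5000	8.4349203881e-01
36.7500	8.3012818631e-01
37.0000	8.1711847211e-01
37.2500	8.0445112202e-01
37.5000	7.9211482959e-01
37.7500	7.8009873313e-01
38.0000	7.6839239588e-01
38.2500	7.5698578627e-01
38.5000	7.4586926325e-01
38.7500	7.3503355179e-01
39.0000	7.2446973399e-01
39.2500	7.1416922856e-01
39.5000	7.0412377725e-01
39.7500	6.9432543143e-01
40.0000	6.8476653804e-01
40.2500	6.7543972740e-01
40.5000	6.6633789997e-01
40.7500	6.5745421647e-01
41.0000	6.4878208393e-01
41.2500	6.4031514982e-01
41.5000	6.3204728811e-01
41.7500	6.2397259171e-01
42.0000	6.1608536178e-01
42.2500	6.0838010224e-01
42.5000	6.0085150799e-01
42.7500	5.9349445925e-01
43.0000	5.8630401433e-01
43.2500	5.7927540008e-01
43.5000	5.7240400873e-01
43.7500	5.6568538770e-01
44.0000	5.5911523639e-01
44.2500	5.5268939780e-01
44.5000	5.4640385489e-01
44.7500	5.4025472394e-01
45.0000	5.3423825084e-01
45.2500	5.2835080291e-01
45.5000	5.2258886946e-01
45.7500	5.1694905145e-01
46.0000	5.1142806109e-01
46.2500	5.0602271687e-01
46.5000	5.0072993868e-01
46.7500	4.9554674354e-01
47.0000	4.9047024616e-01
47.2500	4.8549764870e-01
47.5000	4.8062624329e-01
47.7500	4.7585340572e-01
48.0000	4.7117659450e-01
48.2500	4.6659334500e-01
48.5000	4.6210126811e-01
48.7500	4.5769805083e-01
49.0000	4.5338144601e-01
49.2500	4.4914927873e-01
49.5000	4.4499943604e-01
49.7500	4.4092987167e-01
50.0000	4.3693859723e-01
50.2500	4.3302368551e-01
50.5000	4.2918326594e-01
50.7500	4.2541552079e-01
51.0000	4.2171868721e-01
51.2500	4.1809105517e-01
51.5000	4.1453096054e-01
51.7500	4.1103679040e-01
52.0000	4.0760697572e-01
52.2500	4.0423999307e-01
52.5000	4.0093436354e-01
52.7500	3.9768864750e-01
53.0000	3.9450144779e-01
53.2500	3.9137140594e-01
53.5000	3.8829720008e-01
53.7500	3.8527754780e-01
54.0000	3.8231119860e-01
54.2500	3.7939693912e-01
54.5000	3.7653358787e-01
54.7500	3.7371999586e-01
55.0000	3.7095504453e-01
55.2500	3.6823764722e-01
55.5000	3.6556674516e-01
55.7500	3.6294130752e-01
56.0000	3.6036033178e-01
56.2500	3.5782284184e-01
56.5000	3.5532788689e-01
56.7500	3.5287454159e-01
57.0000	3.5046190503e-01
57.2500	3.4808909926e-01
57.5000	3.4575526835e-01
57.7500	3.4345958029e-01
58.0000	3.4120122287e-01
58.2500	3.3897940522e-01
58.5000	3.3679335687e-01
58.7500	3.3464232689e-01
59.0000	3.3252558279e-01
59.2500	3.3044241112e-01
59.5000	3.2839211524e-01
59.7500	3.2637401727e-01
60.0000	3.2438745520e-01
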
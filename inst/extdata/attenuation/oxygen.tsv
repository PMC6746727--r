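energy_keV	mu_over_rho_cm2_g
15.0000	1.8006336249e+00
15.2500	1.7215687132e+00
15.5000	1.6476194142e+00
15.7500	1.5783779619e+00
16.0000	1.5134748711e+00
16.2500	1.4525748226e+00
16.5000	1.3953730368e+00
16.7500	1.3415921045e+00
17.0000	1.2909791523e+00
17.2500	1.2433033700e+00
17.5000	1.1983537912e+00
17.7500	1.1559373509e+00
18.0000	1.1158771333e+00
18.2500	1.0780108214e+00
18.5000	1.0421893233e+00
18.7500	1.0082755298e+00
19.0000	9.7614320557e-01
19.2500	9.4567600368e-01
19.5000	9.1676657805e-01
19.7500	8.8931577448e-01
20.0000	8.6323192103e-01
20.2500	8.3843017260e-01
20.5000	8.1483193396e-01
20.7500	7.9236431857e-01
21.0000	7.7095968260e-01
21.2500	7.5055518875e-01
21.5000	7.3109240502e-01
21.7500	7.1251695983e-01
22.0000	6.9477821214e-01
22.2500	6.7782895180e-01
22.5000	6.6162514521e-01
22.7500	6.4612567008e-01
23.0000	6.3129211328e-01
23.2500	6.1708855025e-01
23.5000	6.0348136381e-01
23.7500	5.9043907430e-01
24.0000	5.7793218403e-01
24.2500	5.6593302794e-01
24.5000	5.5441564669e-01
24.7500	5.4335566313e-01
25.0000	5.3273017113e-01
25.2500	5.2251763382e-01
25.5000	5.1269778539e-01
25.7500	5.0325155149e-01
26.0000	4.9416096061e-01
26.2500	4.8540907506e-01
26.5000	4.7697991781e-01
26.7500	4.6884361006e-01
27.0000	4.6094527956e-01
27.2500	4.5333287459e-01
27.5000	4.4599324613e-01
27.7500	4.3891397003e-01
28.0000	4.3208329636e-01
28.2500	4.2549010900e-01
28.5000	4.1912388936e-01
28.7500	4.1297467232e-01
29.0000	4.0703301623e-01
29.2500	4.0128997366e-01
29.5000	3.9573705646e-01
29.7500	3.9036620932e-01
30.0000	3.8516978938e-01
30.2500	3.8014053322e-01
30.5000	3.7527154230e-01
30.7500	3.7055625870e-01
31.0000	3.6598844279e-01
31.2500	3.6156216211e-01
31.5000	3.5727176860e-01
31.7500	3.5311188159e-01
32.0000	3.4907737973e-01
32.2500	3.4516337949e-01
32.5000	3.4136522760e-01
32.7500	3.3767848148e-01
33.0000	3.3409890700e-01
33.2500	3.3062246347e-01
33.5000	3.2724528853e-01
33.7500	3.2396369666e-01
34.0000	3.2077416535e-01
34.2500	3.1767332761e-01
34.5000	3.1465796248e-01
34.7500	3.1172499307e-01
35.0000	3.0887147225e-01
35.2500	3.0609458032e-01
35.5000	3.0339161792e-01
35.7500	3.0075999931e-01
36.0000	2.9819724831e-01
36.2500	2.9570098902e-01
36.5000	2.9326894802e-01
36.7500	2.9089894295e-01
37.0000	2.8858887973e-01
37.2500	2.8633675156e-01
37.5000	2.8414063067e-01
37.7500	2.8199866738e-01
38.0000	2.7990908446e-01
38.2500	2.7787017491e-01
38.5000	2.7588029932e-01
38.7500	2.7393788267e-01
39.0000	2.7204140913e-01
39.2500	2.7018942234e-01
39.5000	2.6838052043e-01
39.7500	2.6661335646e-01
40.0000	2.6488663259e-01
40.2500	2.6319910101e-01
40.5000	2.6154955816e-01
40.7500	2.5993684845e-01
41.0000	2.5835985525e-01
41.2500	2.5681750453e-01
41.5000	2.5530876211e-01
41.7500	2.5383262842e-01
42.0000	2.5238814121e-01
42.2500	2.5097437412e-01
42.5000	2.4959043054e-01
42.7500	2.4823544793e-01
43.0000	2.4690859323e-01
43.2500	2.4560906061e-01
43.5000	2.4433607546e-01
43.7500	2.4308888782e-01
44.0000	2.4186677270e-01
44.2500	2.4066903081e-01
44.5000	2.3949498642e-01
44.7500	2.3834398691e-01
45.0000	2.3721540095e-01
45.2500	2.3610861708e-01
45.5000	2.3502304672e-01
45.7500	2.3395811805e-01
46.0000	2.3291328001e-01
46.2500	2.3188799776e-01
46.5000	2.3088175448e-01
46.7500	2.2989404960e-01
47.0000	2.2892439973e-01
47.2500	2.2797233449e-01
47.5000	2.2703740112e-01
47.7500	2.2611915913e-01
48.0000	2.2521718281e-01
48.2500	2.2433105951e-01
48.5000	2.2346038872e-01
48.7500	2.2260478372e-01
49.0000	2.2176386734e-01
49.2500	2.2093727549e-01
49.5000	2.2012465547e-01
49.7500	2.1932566455e-01
50.0000	2.1853996917e-01
50.2500	2.1776724836e-01
50.5000	2.1700718893e-01
50.7500	2.1625948604e-01
51.0000	2.1552384444e-01
51.2500	2.1479998033e-01
51.5000	2.1408761421e-01
51.7500	2.1338647736e-01
52.0000	2.1269630645e-01
52.2500	2.1201684743e-01
52.5000	2.1134785367e-01
52.7500	2.1068908357e-01
53.0000	2.1004030484e-01
53.2500	2.0940129051e-01
53.5000	2.0877181872e-01
53.7500	2.0815167632e-01
54.0000	2.0754065433e-01
54.2500	2.0693855003e-01
54.5000	2.0634516640e-01
54.7500	2.0576031120e-01
55.0000	2.0518379789e-01
55.2500	2.0461544483e-01
55.5000	2.0405507587e-01
55.7500	2.0350251862e-01
56.0000	2.0295760544e-01
56.2500	2.0242017402e-01
56.5000	2.0189006442e-01
56.7500	2.0136712380e-01
57.0000	2.0085120117e-01
57.2500	2.0034214957e-01
57.5000	1.9983982676e-01
57.7500	1.9934409291e-01
58.0000	1.9885481379e-01
58.2500	1.9837185677e-01
58.5000	1.9789509250e-01
58.7500	1.9742439715e-01
59.0000	1.9695964684e-01
59.2500	1.9650072371e-01
59.5000	1.9604751054e-01
59.7500	1.9559989487e-01
60.0000	1.9515776588e-01
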
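energy_keV	mu_over_rho_cm2_g
15.0000	1.6698332262e+00
15.2500	1.5985040734e+00
15.5000	1.5317595401e+00
15.7500	1.4692300649e+00
16.0000	1.4105869437e+00
16.2500	1.3555382183e+00
16.5000	1.3038116201e+00
16.7500	1.2551592297e+00
17.0000	1.2093549635e+00
17.2500	1.1661923802e+00
17.5000	1.1254827128e+00
17.7500	1.0870531428e+00
18.0000	1.0507452454e+00
18.2500	1.0164136133e+00
18.5000	9.8392463389e-01
18.7500	9.5315538648e-01
19.0000	9.2399265686e-01
19.2500	8.9633205974e-01
19.5000	8.7007724864e-01
19.7500	8.4513919789e-01
20.0000	8.2143556902e-01
20.2500	7.9889012797e-01
20.5000	7.7743223011e-01
20.7500	7.5699633994e-01
21.0000	7.3752161347e-01
21.2500	7.1895151003e-01
21.5000	7.0123343577e-01
21.7500	6.8431843401e-01
22.0000	6.6816089126e-01
22.2500	6.5271827126e-01
22.5000	6.3795088500e-01
22.7500	6.2382165736e-01
23.0000	6.1029591065e-01
23.2500	5.9734125302e-01
23.5000	5.8492737006e-01
23.7500	5.7302584232e-01
24.0000	5.6161003112e-01
24.2500	5.5065494589e-01
24.5000	5.4013712955e-01
24.7500	5.3003454857e-01
25.0000	5.2032649317e-01
25.2500	5.1099348607e-01
25.5000	5.0201719445e-01
25.7500	4.9338035840e-01
26.0000	4.8506671223e-01
26.2500	4.7706092161e-01
26.5000	4.6934851864e-01
26.7500	4.6190275776e-01
27.0000	4.5467480943e-01
27.2500	4.4770678140e-01
27.5000	4.4098676521e-01
27.7500	4.3450350554e-01
28.0000	4.2824635613e-01
28.2500	4.2220524267e-01
28.5000	4.1637062965e-01
28.7500	4.1073348225e-01
29.0000	4.0528523828e-01
29.2500	4.0001778170e-01
29.5000	3.9492341195e-01
29.7500	3.8999482002e-01
30.0000	3.8522506889e-01
30.2500	3.8060756612e-01
30.5000	3.7613604841e-01
30.7500	3.7180456088e-01
31.0000	3.6760743724e-01
31.2500	3.6353928881e-01
31.5000	3.5959498446e-01
31.7500	3.5576963598e-01
32.0000	3.5205858909e-01
32.2500	3.4845740573e-01
32.5000	3.4496185620e-01
32.7500	3.4156790212e-01
33.0000	3.3827169413e-01
33.2500	3.3506955757e-01
33.5000	3.3195798060e-01
33.7500	3.2893361103e-01
34.0000	3.2599324494e-01
34.2500	3.2313381950e-01
34.5000	3.2035240476e-01
34.7500	3.1764620070e-01
35.0000	3.1501252593e-01
35.2500	3.1244881449e-01
35.5000	3.0995260970e-01
35.7500	3.0752155803e-01
36.0000	3.0515340567e-01
36.2500	3.0284599008e-01
36.5000	3.0059724118e-01
36.7500	2.9840517229e-01
37.0000	2.9626787683e-01
37.2500	2.9418352730e-01
37.5000	2.9215036835e-01
37.7500	2.9016671550e-01
38.0000	2.8823095022e-01
38.2500	2.8634151792e-01
38.5000	2.8449692525e-01
38.7500	2.8269573746e-01
39.0000	2.8093657385e-01
39.2500	2.7921810773e-01
39.5000	2.7753906213e-01
39.7500	2.7589820968e-01
40.0000	2.7429436819e-01
40.2500	2.7272640050e-01
40.5000	2.7119321020e-01
40.7500	2.6969374414e-01
41.0000	2.6822698498e-01
41.2500	2.6679195401e-01
41.5000	2.6538770849e-01
41.7500	2.6401333788e-01
42.0000	2.6266796528e-01
42.2500	2.6135074610e-01
42.5000	2.6006086354e-01
42.7500	2.5879753137e-01
43.0000	2.5755999017e-01
43.2500	2.5634750597e-01
43.5000	2.5515937218e-01
43.7500	2.5399490559e-01
44.0000	2.5285344529e-01
44.2500	2.5173435404e-01
44.5000	2.5063701592e-01
44.7500	2.4956083594e-01
45.0000	2.4850523878e-01
45.2500	2.4746966723e-01
45.5000	2.4645358452e-01
45.7500	2.4545646979e-01
46.0000	2.4447782036e-01
46.2500	2.4351714907e-01
46.5000	2.4257398488e-01
46.7500	2.4164787155e-01
47.0000	2.4073836828e-01
47.2500	2.3984504677e-01
47.5000	2.3896749403e-01
47.7500	2.3810530887e-01
48.0000	2.3725810320e-01
48.2500	2.3642550092e-01
48.5000	2.3560713726e-01
48.7500	2.3480265954e-01
49.0000	2.3401172433e-01
49.2500	2.3323399986e-01
49.5000	2.3246916465e-01
49.7500	2.3171690643e-01
50.0000	2.3097692154e-01
50.2500	2.3024891735e-01
50.5000	2.2953260846e-01
50.7500	2.2882771748e-01
51.0000	2.2813397549e-01
51.2500	2.2745112370e-01
51.5000	2.2677890774e-01
51.7500	2.2611708274e-01
52.0000	2.2546540912e-01
52.2500	2.2482365555e-01
52.5000	2.2419159716e-01
52.7500	2.2356901438e-01
53.0000	2.2295569549e-01
53.2500	2.2235143386e-01
53.5000	2.2175602780e-01
53.7500	2.2116928309e-01
54.0000	2.2059100954e-01
54.2500	2.2002102281e-01
54.5000	2.1945914351e-01
54.7500	2.1890519684e-01
55.0000	2.1835901306e-01
55.2500	2.1782042703e-01
55.5000	2.1728927831e-01
55.7500	2.1676541027e-01
56.0000	2.1624867060e-01
56.2500	2.1573891149e-01
56.5000	2.1523598783e-01
56.7500	2.1473976038e-01
57.0000	2.1425009202e-01
57.2500	2.1376684924e-01
57.5000	2.1328990274e-01
57.7500	2.1281912568e-01
58.0000	2.1235439585e-01
58.2500	2.1189559290e-01
58.5000	2.1144259945e-01
58.7500	2.1099530286e-01
59.0000	2.1055359096e-01
59.2500	2.1011735649e-01
59.5000	2.0968649334e-01
59.7500	2.0926089918e-01
60.0000	2.0884047364e-01
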
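energy_keV	mu_over_rho_cm2_g
15.0000	1.5893666096e+00
15.2500	1.5212715944e+00
15.5000	1.4575480406e+00
15.7500	1.3978494326e+00
16.0000	1.3418616629e+00
16.2500	1.2892995509e+00
16.5000	1.2399037873e+00
16.7500	1.1934382595e+00
17.0000	1.1496876464e+00
17.2500	1.1084553323e+00
17.5000	1.0695615383e+00
17.7500	1.0328416693e+00
18.0000	9.9814483309e-01
18.2500	9.6533253960e-01
18.5000	9.3427752302e-01
18.7500	9.0486269525e-01
19.0000	8.7698021774e-01
19.2500	8.5053065001e-01
19.5000	8.2542220937e-01
19.7500	8.0157007855e-01
20.0000	7.7889581097e-01
20.2500	7.5732676839e-01
20.5000	7.3679563543e-01
20.7500	7.1723995952e-01
21.0000	6.9860175603e-01
21.2500	6.8082713372e-01
21.5000	6.6386596331e-01
21.7500	6.4767157646e-01
22.0000	6.3220048716e-01
22.2500	6.1741214045e-01
22.5000	6.0326869088e-01
22.7500	5.8973478778e-01
23.0000	5.7677738420e-01
23.2500	5.6436556844e-01
23.5000	5.5247040369e-01
23.7500	5.4106477767e-01
24.0000	5.3012327652e-01
24.2500	5.1962205512e-01
24.5000	5.0953872930e-01
24.7500	4.9985227386e-01
25.0000	4.9054292139e-01
25.2500	4.8159208401e-01
25.5000	4.7298225803e-01
25.7500	4.6469696592e-01
26.0000	4.5672067917e-01
26.2500	4.4903875502e-01
26.5000	4.4163737827e-01
26.7500	4.3449345227e-01
27.0000	4.2756705388e-01
27.2500	4.2088826560e-01
27.5000	4.1444578146e-01
27.7500	4.0822891562e-01
28.0000	4.0222755960e-01
28.2500	3.9643214464e-01
28.5000	3.9083361444e-01
28.7500	3.8542338678e-01
29.0000	3.8019332546e-01
29.2500	3.7513572036e-01
29.5000	3.7024325224e-01
29.7500	3.6550897662e-01
30.0000	3.6092629663e-01
30.2500	3.5648894984e-01
30.5000	3.5219098163e-01
30.7500	3.4802673032e-01
31.0000	3.4399080840e-01
31.2500	3.4007809562e-01
31.5000	3.3628371158e-01
31.7500	3.3260301247e-01
32.0000	3.2903157131e-01
32.2500	3.2556517022e-01
32.5000	3.2219978853e-01
32.7500	3.1893158837e-01
33.0000	3.1575691160e-01
33.2500	3.1267226554e-01
33.5000	3.0967431634e-01
33.7500	3.0675987588e-01
34.0000	3.0392590262e-01
34.2500	3.0116948710e-01
34.5000	2.9848784928e-01
34.7500	2.9587832988e-01
35.0000	2.9333838419e-01
35.2500	2.9086557802e-01
35.5000	2.8845758109e-01
35.7500	2.8611216027e-01
36.0000	2.8382718210e-01
36.2500	2.8160059554e-01
36.5000	2.7943043922e-01
36.7500	2.7731483285e-01
37.0000	2.7525197095e-01
37.2500	2.7324012477e-01
37.5000	2.7127763352e-01
37.7500	2.6936290733e-01
38.0000	2.6749441455e-01
38.2500	2.6567068872e-01
38.5000	2.6389031831e-01
38.7500	2.6215195229e-01
39.0000	2.6045428781e-01
39.2500	2.5879607443e-01
39.5000	2.5717611076e-01
39.7500	2.5559324222e-01
40.0000	2.5404635648e-01
40.2500	2.5253438572e-01
40.5000	2.5105629978e-01
40.7500	2.4961111150e-01
41.0000	2.4819786626e-01
41.2500	2.4681564803e-01
41.5000	2.4546357350e-01
41.7500	2.4414079230e-01
42.0000	2.4284648532e-01
42.2500	2.4157986306e-01
42.5000	2.4034016593e-01
42.7500	2.3912666020e-01
43.0000	2.3793863949e-01
43.2500	2.3677542208e-01
43.5000	2.3563635055e-01
43.7500	2.3452079341e-01
44.0000	2.3342813579e-01
44.2500	2.3235779027e-01
44.5000	2.3130918693e-01
44.7500	2.3028177643e-01
45.0000	2.2927502934e-01
45.2500	2.2828843248e-01
45.5000	2.2732149166e-01
45.7500	2.2637372965e-01
46.0000	2.2544468493e-01
46.2500	2.2453391285e-01
46.5000	2.2364098137e-01
46.7500	2.2276547657e-01
47.0000	2.2190699470e-01
47.2500	2.2106514829e-01
47.5000	2.2023956080e-01
47.7500	2.1942987000e-01
48.0000	2.1863572431e-01
48.2500	2.1785678409e-01
48.5000	2.1709272107e-01
48.7500	2.1634321762e-01
49.0000	2.1560796619e-01
49.2500	2.1488666940e-01
49.5000	2.1417903964e-01
49.7500	2.1348479867e-01
50.0000	2.1280367665e-01
50.2500	2.1213541430e-01
50.5000	2.1147975704e-01
50.7500	2.1083646124e-01
51.0000	2.1020529040e-01
51.2500	2.0958601514e-01
51.5000	2.0897841482e-01
51.7500	2.0838227339e-01
52.0000	2.0779738270e-01
52.2500	2.0722354292e-01
52.5000	2.0666055625e-01
52.7500	2.0610823522e-01
53.0000	2.0556639651e-01
53.2500	2.0503486295e-01
53.5000	2.0451346171e-01
53.7500	2.0400202651e-01
54.0000	2.0350039543e-01
54.2500	2.0300841371e-01
54.5000	2.0252592898e-01
54.7500	2.0205279340e-01
55.0000	2.0158886563e-01
55.2500	2.0113400746e-01
55.5000	2.0068808455e-01
55.7500	2.0025096728e-01
56.0000	1.9982253130e-01
56.2500	1.9940265386e-01
56.5000	1.9899121639e-01
56.7500	1.9858810542e-01
57.0000	1.9819321016e-01
57.2500	1.9780642232e-01
57.5000	1.9742763735e-01
57.7500	1.9705675545e-01
58.0000	1.9669367825e-01
58.2500	1.9633831054e-01
58.5000	1.9599056022e-01
58.7500	1.9565033824e-01
59.0000	1.9531755838e-01
59.2500	1.9499213656e-01
59.5000	1.9467399268e-01
59.7500	1.9436304520e-01
60.0000	1.9405922074e-01
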
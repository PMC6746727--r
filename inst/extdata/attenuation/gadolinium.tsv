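energy_keV	mu_over_rho_cm2_g
15.0000	9.2478517839e+01
15.2500	8.8538879555e+01
15.5000	8.4825340073e+01
15.7500	8.1321692220e+01
16.0000	7.8010147010e+01
16.2500	7.4878406724e+01
16.5000	7.1916493891e+01
16.7500	6.9112894900e+01
17.0000	6.6454113538e+01
17.2500	6.3933674548e+01
17.5000	6.1542582493e+01
17.7500	5.9272527929e+01
18.0000	5.7115839171e+01
18.2500	5.5065425574e+01
18.5000	5.3114726542e+01
18.7500	5.1257665557e+01
19.0000	4.9488608873e+01
19.2500	4.7802328056e+01
19.5000	4.6193966173e+01
19.7500	4.4659007249e+01
20.0000	4.3193248466e+01
20.2500	4.1792774964e+01
20.5000	4.0453937051e+01
20.7500	3.9173329252e+01
21.0000	3.7947771474e+01
21.2500	3.6774291601e+01
21.5000	3.5650109746e+01
21.7500	3.4572623866e+01
22.0000	3.3539396508e+01
22.2500	3.2548142734e+01
22.5000	3.1596719034e+01
22.7500	3.0683113225e+01
23.0000	2.9805434988e+01
23.2500	2.8961907438e+01
23.5000	2.8150859091e+01
23.7500	2.7370716669e+01
24.0000	2.6619998408e+01
24.2500	2.5897307796e+01
24.5000	2.5201327960e+01
24.7500	2.4530816310e+01
25.0000	2.3884599729e+01
25.2500	2.3261570041e+01
25.5000	2.2660677772e+01
25.7500	2.2080935228e+01
26.0000	2.1521404983e+01
26.2500	2.0981199491e+01
26.5000	2.0459478883e+01
26.7500	1.9955198455e+01
27.0000	1.9466948472e+01
27.2500	1.8995055427e+01
27.5000	1.8538827993e+01
27.7500	1.8097610048e+01
28.0000	1.7670778533e+01
28.2500	1.7257741582e+01
28.5000	1.6857936601e+01
28.7500	1.6470828679e+01
29.0000	1.6095908931e+01
29.2500	1.5732693072e+01
29.5000	1.5380719980e+01
29.7500	1.5039550430e+01
30.0000	1.4708765906e+01
30.2500	1.4387967404e+01
30.5000	1.4076774422e+01
30.7500	1.3774823932e+01
31.0000	1.3481769429e+01
31.2500	1.3197280119e+01
31.5000	1.2920804591e+01
31.7500	1.2652023559e+01
32.0000	1.2390937702e+01
32.2500	1.2137268766e+01
32.5000	1.1890750627e+01
32.7500	1.1651128633e+01
33.0000	1.1418159165e+01
33.2500	1.1191608933e+01
33.5000	1.0971254534e+01
33.7500	1.0756881953e+01
34.0000	1.0548286087e+01
34.2500	1.0345270332e+01
34.5000	1.0147415670e+01
34.7500	9.9545970816e+00
35.0000	9.7668433384e+00
35.2500	9.5839863004e+00
35.5000	9.4058645739e+00
35.7500	9.2323231884e+00
36.0000	9.0632133183e+00
36.2500	8.8983919315e+00
36.5000	8.7371551633e+00
36.7500	8.5798482781e+00
37.0000	8.4264698906e+00
37.2500	8.2768960963e+00
37.5000	8.1310077466e+00
37.7500	7.9886901491e+00
38.0000	7.8498329434e+00
38.2500	7.7143298628e+00
38.5000	7.5820785845e+00
38.7500	7.4529805637e+00
39.0000	7.3269408297e+00
39.2500	7.2038678960e+00
39.5000	7.0836735457e+00
39.7500	6.9662727437e+00
40.0000	6.8515834766e+00
40.2500	6.7395266317e+00
40.5000	6.6300258975e+00
40.7500	6.5230076086e+00
41.0000	6.4184006736e+00
41.2500	6.3161364366e+00
41.5000	6.2161486335e+00
41.7500	6.1183732325e+00
42.0000	6.0227483629e+00
42.2500	5.9292142763e+00
42.5000	5.8377132002e+00
42.7500	5.7481892962e+00
43.0000	5.6605885632e+00
43.2500	5.5748588023e+00
43.5000	5.4909494874e+00
43.7500	5.4088117672e+00
44.0000	5.3283983640e+00
44.2500	5.2496635132e+00
44.5000	5.1725629137e+00
44.7500	5.0970536856e+00
45.0000	5.0230942906e+00
45.2500	4.9506445121e+00
45.5000	4.8796653837e+00
45.7500	4.8101191427e+00
46.0000	4.7419692090e+00
46.2500	4.6751801321e+00
46.5000	4.6097175258e+00
46.7500	4.5455480659e+00
47.0000	4.4826394380e+00
47.2500	4.4209602931e+00
47.5000	4.3604802222e+00
47.7500	4.3011697516e+00
48.0000	4.2430002198e+00
48.2500	4.1859438715e+00
48.5000	4.1299737327e+00
48.7391	4.0774359689e+00
48.7500	4.0750636382e+00
48.7891	4.0665698893e+00
48.8391	4.0557450492e+00
48.8891	4.0449612285e+00
48.9391	4.0342182393e+00
48.9891	4.0235158890e+00
49.0000	4.0211881494e+00
49.0391	4.0128539671e+00
49.0891	4.0022322971e+00
49.1391	3.9916506818e+00
49.1891	3.9811089153e+00
49.2391	3.9706068156e+00
49.2500	3.9683226068e+00
49.2891	3.9601441941e+00
49.3391	3.9497208666e+00
49.3891	3.9393366421e+00
49.4391	3.9289913267e+00
49.4891	3.9186847344e+00
49.5000	3.9164430220e+00
49.5391	3.9084167017e+00
49.5891	3.8981870220e+00
49.6391	3.8879955272e+00
49.6891	3.8778420269e+00
49.7391	3.8677263433e+00
49.7500	3.8655261332e+00
49.7891	3.8576483056e+00
49.8391	3.8476077279e+00
49.8891	3.8376044270e+00
49.9391	3.8276382420e+00
49.9891	3.8177089836e+00
50.0000	3.8155492906e+00
50.0391	3.8078164887e+00
50.0891	3.7979605765e+00
50.1391	3.7881410757e+00
50.1891	3.7783578273e+00
50.2391	3.7686495569e+00
50.2391	1.8529413664e+01
50.2500	1.8519532141e+01
50.2891	1.8483481827e+01
50.3391	1.8437515778e+01
50.3891	1.8391699666e+01
50.4391	1.8346032875e+01
50.4891	1.8300514815e+01
50.5000	1.8290611564e+01
50.5391	1.8255144868e+01
50.5891	1.8209922436e+01
50.6391	1.8164846925e+01
50.6891	1.8119917742e+01
50.7391	1.8075134289e+01
50.7500	1.8065390786e+01
50.7891	1.8030495980e+01
50.8391	1.7986002235e+01
50.8891	1.7941652456e+01
50.9391	1.7897446077e+01
50.9891	1.7853382516e+01
51.0000	1.7843795564e+01
51.0391	1.7809461197e+01
51.0891	1.7765681549e+01
51.1391	1.7722043009e+01
51.1891	1.7678544997e+01
51.2391	1.7635186962e+01
51.2500	1.7625753437e+01
51.2891	1.7591968339e+01
51.3391	1.7548888565e+01
51.3891	1.7505947089e+01
51.4391	1.7463143362e+01
51.4891	1.7420476829e+01
51.5000	1.7411193686e+01
51.5391	1.7377946946e+01
51.5891	1.7335553162e+01
51.6391	1.7293294937e+01
51.6891	1.7251171738e+01
51.7500	1.7200047285e+01
52.0000	1.6992246848e+01
52.2500	1.6787726594e+01
52.5000	1.6586422295e+01
52.7500	1.6387758086e+01
53.0000	1.6189479012e+01
53.2500	1.5994467772e+01
53.5000	1.5802656338e+01
53.7500	1.5613978390e+01
54.0000	1.5428369295e+01
54.2500	1.5245765998e+01
54.5000	1.5066107025e+01
54.7500	1.4889332427e+01
55.0000	1.4715383720e+01
55.2500	1.4544203860e+01
55.5000	1.4375737186e+01
55.7500	1.4209929395e+01
56.0000	1.4046727500e+01
56.2500	1.3886079796e+01
56.5000	1.3727935794e+01
56.7500	1.3572246235e+01
57.0000	1.3418963029e+01
57.2500	1.3268039199e+01
57.5000	1.3119428916e+01
57.7500	1.2973087397e+01
58.0000	1.2828970911e+01
58.2500	1.2687036755e+01
58.5000	1.2547243216e+01
58.7500	1.2409549541e+01
59.0000	1.2273915904e+01
59.2500	1.2140303402e+01
59.5000	1.2008674029e+01
59.7500	1.1878990619e+01
60.0000	1.1751216874e+01
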
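energy_keV	mu_over_rho_cm2_g
15.0000	1.6411879786e+00
15.2500	1.5709331523e+00
15.5000	1.5052215728e+00
15.7500	1.4436911042e+00
16.0000	1.3860136080e+00
16.2500	1.3318912881e+00
16.5000	1.2810534704e+00
16.7500	1.2332537888e+00
17.0000	1.1882676668e+00
17.2500	1.1458901225e+00
17.5000	1.1059337972e+00
17.7500	1.0682272301e+00
18.0000	1.0326133027e+00
18.2500	9.9894786159e-01
18.5000	9.6709849838e-01
18.7500	9.3694344656e-01
19.0000	9.0837059674e-01
19.2500	8.8127662126e-01
19.5000	8.5556618616e-01
19.7500	8.3115123264e-01
20.0000	8.0795034686e-01
20.2500	7.8588817787e-01
20.5000	7.6489492522e-01
20.7500	7.4490585832e-01
21.0000	7.2586090262e-01
21.2500	7.0770425223e-01
21.5000	6.9038401359e-01
21.7500	6.7385189919e-01
22.0000	6.5806293460e-01
22.2500	6.4297519236e-01
22.5000	6.2854956608e-01
22.7500	6.1474953489e-01
23.0000	6.0154098396e-01
23.2500	5.8889200849e-01
23.5000	5.7677275291e-01
23.7500	5.6515525995e-01
24.0000	5.5401333252e-01
24.2500	5.4332240110e-01
24.5000	5.3305941101e-01
24.7500	5.2320271271e-01
25.0000	5.1373196304e-01
25.2500	5.0462803493e-01
25.5000	4.9587293010e-01
25.7500	4.8744970839e-01
26.0000	4.7934240913e-01
26.2500	4.7153598971e-01
26.5000	4.6401626073e-01
26.7500	4.5675668671e-01
27.0000	4.4970853566e-01
27.2500	4.4291438981e-01
27.5000	4.3636257131e-01
27.7500	4.3004204604e-01
28.0000	4.2394237867e-01
28.2500	4.1805369676e-01
28.5000	4.1236665853e-01
28.7500	4.0687241373e-01
29.0000	4.0156257701e-01
29.2500	3.9642920194e-01
29.5000	3.9146474997e-01
29.7500	3.8666206694e-01
30.0000	3.8201436502e-01
30.2500	3.7751519335e-01
30.5000	3.7315842509e-01
30.7500	3.6893823595e-01
31.0000	3.6484908427e-01
31.2500	3.6088570123e-01
31.5000	3.5704307056e-01
31.7500	3.5331641346e-01
32.0000	3.4970118144e-01
32.2500	3.4619303722e-01
32.5000	3.4278784800e-01
32.7500	3.3948166810e-01
33.0000	3.3627073698e-01
33.2500	3.3315146588e-01
33.5000	3.3012042442e-01
33.7500	3.2717433927e-01
34.0000	3.2431008186e-01
34.2500	3.2152466178e-01
34.5000	3.1881521823e-01
34.7500	3.1617901845e-01
35.0000	3.1361344485e-01
35.2500	3.1111599305e-01
35.5000	3.0868426554e-01
35.7500	3.0631596570e-01
36.0000	3.0400889422e-01
36.2500	3.0176094086e-01
36.5000	2.9957008638e-01
36.7500	2.9743439240e-01
37.0000	2.9535199898e-01
37.2500	2.9332112365e-01
37.5000	2.9134005416e-01
37.7500	2.8940714760e-01
38.0000	2.8752082540e-01
38.2500	2.8567957137e-01
38.5000	2.8388192934e-01
38.7500	2.8212650033e-01
39.0000	2.8041193793e-01
39.2500	2.7873694852e-01
39.5000	2.7710028694e-01
39.7500	2.7550075672e-01
40.0000	2.7393720508e-01
40.2500	2.7240852362e-01
40.5000	2.7091364327e-01
40.7500	2.6945153755e-01
41.0000	2.6802121457e-01
41.2500	2.6662172030e-01
41.5000	2.6525213608e-01
41.7500	2.6391157398e-01
42.0000	2.6259917925e-01
42.2500	2.6131412900e-01
42.5000	2.6005562673e-01
42.7500	2.5882290624e-01
43.0000	2.5761522749e-01
43.2500	2.5643187464e-01
43.5000	2.5527215956e-01
43.7500	2.5413541601e-01
44.0000	2.5302099995e-01
44.2500	2.5192829014e-01
44.5000	2.5085668630e-01
44.7500	2.4980560861e-01
45.0000	2.4877449623e-01
45.2500	2.4776280592e-01
45.5000	2.4677001478e-01
45.7500	2.4579561479e-01
46.0000	2.4483911638e-01
46.2500	2.4390004436e-01
46.5000	2.4297793957e-01
46.7500	2.4207235725e-01
47.0000	2.4118286794e-01
47.2500	2.4030905372e-01
47.5000	2.3945051230e-01
47.7500	2.3860685230e-01
48.0000	2.3777769547e-01
48.2500	2.3696267516e-01
48.5000	2.3616143549e-01
48.7500	2.3537363286e-01
49.0000	2.3459893210e-01
49.2500	2.3383700971e-01
49.5000	2.3308755227e-01
49.7500	2.3235025524e-01
50.0000	2.3162482219e-01
50.2500	2.3091096791e-01
50.5000	2.3020841408e-01
50.7500	2.2951688979e-01
51.0000	2.2883613267e-01
51.2500	2.2816589051e-01
51.5000	2.2750591490e-01
51.7500	2.2685596703e-01
52.0000	2.2621581288e-01
52.2500	2.2558522666e-01
52.5000	2.2496398914e-01
52.7500	2.2435188562e-01
53.0000	2.2374870962e-01
53.2500	2.2315425942e-01
53.5000	2.2256833781e-01
53.7500	2.2199075533e-01
54.0000	2.2142132622e-01
54.2500	2.2085987029e-01
54.5000	2.2030621239e-01
54.7500	2.1976018164e-01
55.0000	2.1922161221e-01
55.2500	2.1869034263e-01
55.5000	2.1816621631e-01
55.7500	2.1764907997e-01
56.0000	2.1713878459e-01
56.2500	2.1663518585e-01
56.5000	2.1613814156e-01
56.7500	2.1564751584e-01
57.0000	2.1516317440e-01
57.2500	2.1468498661e-01
57.5000	2.1421282597e-01
57.7500	2.1374656815e-01
58.0000	2.1328609380e-01
58.2500	2.1283128495e-01
58.5000	2.1238202659e-01
58.7500	2.1193820860e-01
59.0000	2.1149972079e-01
59.2500	2.1106645837e-01
59.5000	2.1063831705e-01
59.7500	2.1021519685e-01
60.0000	2.0979699915e-01
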
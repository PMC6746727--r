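energy_keV	mu_over_rho_cm2_g
15.0000	9.6205371993e-01
15.2500	9.2509918718e-01
15.5000	8.9052893664e-01
15.7500	8.5815216364e-01
16.0000	8.2779609123e-01
16.2500	7.9930402118e-01
16.5000	7.7253361101e-01
16.7500	7.4735538224e-01
17.0000	7.2365136942e-01
17.2500	7.0131395815e-01
17.5000	6.8024483411e-01
17.7500	6.6035406703e-01
18.0000	6.4155928423e-01
18.2500	6.2378494145e-01
18.5000	6.0696167505e-01
18.7500	5.9102571688e-01
19.0000	5.7591837597e-01
19.2500	5.6158557377e-01
19.5000	5.4797742549e-01
19.7500	5.3504786638e-01
20.0000	5.2275431421e-01
20.2500	5.1105736470e-01
20.5000	4.9992051995e-01
20.7500	4.8930993877e-01
21.0000	4.7919421464e-01
21.2500	4.6954417415e-01
21.5000	4.6033269174e-01
21.7500	4.5153452603e-01
22.0000	4.4312616521e-01
22.2500	4.3508569234e-01
22.5000	4.2739266140e-01
22.7500	4.2002797921e-01
23.0000	4.1297380506e-01
23.2500	4.0621345597e-01
23.5000	3.9973131597e-01
23.7500	3.9351276095e-01
24.0000	3.8754408453e-01
24.2500	3.8181243078e-01
24.5000	3.7630573296e-01
24.7500	3.7101265850e-01
25.0000	3.6592255713e-01
25.2500	3.6102541299e-01
25.5000	3.5631179812e-01
25.7500	3.5177283814e-01
26.0000	3.4740017045e-01
26.2500	3.4318591136e-01
26.5000	3.3912262265e-01
26.7500	3.3519626900e-01
27.0000	3.3138097228e-01
27.2500	3.2769957233e-01
27.5000	3.2414593743e-01
27.7500	3.2071427113e-01
28.0000	3.1739909261e-01
28.2500	3.1419521582e-01
28.5000	3.1109773154e-01
28.7500	3.0810199015e-01
29.0000	3.0520358510e-01
29.2500	3.0239833947e-01
29.5000	2.9968229096e-01
29.7500	2.9705167958e-01
30.0000	2.9450293541e-01
30.2500	2.9203266855e-01
30.5000	2.8963765716e-01
30.7500	2.8731483853e-01
31.0000	2.8506129909e-01
31.2500	2.8287426831e-01
31.5000	2.8075110794e-01
31.7500	2.7868930602e-01
32.0000	2.7668646972e-01
32.2500	2.7474031867e-01
32.5000	2.7284867971e-01
32.7500	2.7100947742e-01
33.0000	2.6922073556e-01
33.2500	2.6748056586e-01
33.5000	2.6578716540e-01
33.7500	2.6413881260e-01
34.0000	2.6253386292e-01
34.2500	2.6097074418e-01
34.5000	2.5944795317e-01
34.7500	2.5796405226e-01
35.0000	2.5651766625e-01
35.2500	2.5510747889e-01
35.5000	2.5373223017e-01
35.7500	2.5239071293e-01
36.0000	2.5108177213e-01
36.2500	2.4980429918e-01
36.5000	2.4855723260e-01
36.7500	2.4733955487e-01
37.0000	2.4615028883e-01
37.2500	2.4498849826e-01
37.5000	2.4385328437e-01
37.7500	2.4274378456e-01
38.0000	2.4165917023e-01
38.2500	2.4059864560e-01
38.5000	2.3956144618e-01
38.7500	2.3854683780e-01
39.0000	2.3755411410e-01
39.2500	2.3658259660e-01
39.5000	2.3563163237e-01
39.7500	2.3470059349e-01
40.0000	2.3378887614e-01
40.2500	2.3289589867e-01
40.5000	2.3202110074e-01
40.7500	2.3116394468e-01
41.0000	2.3032391076e-01
41.2500	2.2950049915e-01
41.5000	2.2869322806e-01
41.7500	2.2790163315e-01
42.0000	2.2712526704e-01
42.2500	2.2636369816e-01
42.5000	2.2561651039e-01
42.7500	2.2488330266e-01
43.0000	2.2416368737e-01
43.2500	2.2345729117e-01
43.5000	2.2276375287e-01
43.7500	2.2208272533e-01
44.0000	2.2141387110e-01
44.2500	2.2075686616e-01
44.5000	2.2011139683e-01
44.7500	2.1947716016e-01
45.0000	2.1885386363e-01
45.2500	2.1824122360e-01
45.5000	2.1763896680e-01
45.7500	2.1704682913e-01
46.0000	2.1646455393e-01
46.2500	2.1589189458e-01
46.5000	2.1532861192e-01
46.7500	2.1477447390e-01
47.0000	2.1422925647e-01
47.2500	2.1369274285e-01
47.5000	2.1316472297e-01
47.7500	2.1264499385e-01
48.0000	2.1213335847e-01
48.2500	2.1162962615e-01
48.5000	2.1113361244e-01
48.7500	2.1064513826e-01
49.0000	2.1016403012e-01
49.2500	2.0969011992e-01
49.5000	2.0922324509e-01
49.7500	2.0876324768e-01
50.0000	2.0830997443e-01
50.2500	2.0786327751e-01
50.5000	2.0742301223e-01
50.7500	2.0698903916e-01
51.0000	2.0656122236e-01
51.2500	2.0613943148e-01
51.5000	2.0572353803e-01
51.7500	2.0531341873e-01
52.0000	2.0490895305e-01
52.2500	2.0451002471e-01
52.5000	2.0411651995e-01
52.7500	2.0372832890e-01
53.0000	2.0334534505e-01
53.2500	2.0296746438e-01
53.5000	2.0259458599e-01
53.7500	2.0222661224e-01
54.0000	2.0186344755e-01
54.2500	2.0150499993e-01
54.5000	2.0115117929e-01
54.7500	2.0080189828e-01
55.0000	2.0045707189e-01
55.2500	2.0011661782e-01
55.5000	1.9978045530e-01
55.7500	1.9944850661e-01
56.0000	1.9912069596e-01
56.2500	1.9879694915e-01
56.5000	1.9847719436e-01
56.7500	1.9816136190e-01
57.0000	1.9784938378e-01
57.2500	1.9754119347e-01
57.5000	1.9723672683e-01
57.7500	1.9693592126e-01
58.0000	1.9663871571e-01
58.2500	1.9634505076e-01
58.5000	1.9605486809e-01
58.7500	1.9576811224e-01
59.0000	1.9548472782e-01
59.2500	1.9520466168e-01
59.5000	1.9492786182e-01
59.7500	1.9465427730e-01
60.0000	1.9438385911e-01
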
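energy_keV	mu_over_rho_cm2_g
15.0000	2.9460186192e+01
15.2500	2.8104846182e+01
15.5000	2.6831667546e+01
15.7500	2.5634513793e+01
16.0000	2.4507791268e+01
16.2500	2.3446393859e+01
16.5000	2.2445654009e+01
16.7500	2.1501299386e+01
17.0000	2.0609414248e+01
17.2500	1.9766405158e+01
17.5000	1.8968955579e+01
17.7500	1.8211373282e+01
18.0000	1.7493958024e+01
18.2500	1.6814080574e+01
18.5000	1.6169315883e+01
18.7500	1.5557424783e+01
19.0000	1.4976337542e+01
19.2500	1.4424139073e+01
19.5000	1.3899055590e+01
19.7500	1.3399442588e+01
20.0000	1.2923776314e+01
20.2500	1.2470638118e+01
20.5000	1.2038708146e+01
20.7500	1.1626760071e+01
21.0000	1.1233651764e+01
21.2500	1.0858318607e+01
21.5000	1.0499767419e+01
21.7500	1.0157070925e+01
22.0000	9.8293626972e+00
22.2500	9.5158325258e+00
22.5000	9.2157222339e+00
22.7500	8.9283217937e+00
23.0000	8.6529657943e+00
23.2500	8.3890302099e+00
23.5000	8.1359294132e+00
23.7500	7.8931134600e+00
24.0000	7.6600655555e+00
24.2500	7.4362997649e+00
24.5000	7.2213588631e+00
24.7500	7.0148123918e+00
25.0000	6.8162548377e+00
25.2500	6.6253039608e+00
25.5000	6.4415992539e+00
25.7500	6.2648005123e+00
26.0000	6.0945865162e+00
26.2500	5.9306537910e+00
26.5000	5.7727154966e+00
26.7500	5.6201165728e+00
27.0000	5.4715420895e+00
27.2500	5.3283381851e+00
27.5000	5.1902643732e+00
27.7500	5.0570929764e+00
28.0000	4.9286083229e+00
28.2500	4.8046060157e+00
28.5000	4.6848922591e+00
28.7500	4.5692832139e+00
29.0000	4.4576044183e+00
29.2500	4.3496902193e+00
29.5000	4.2453832712e+00
29.7500	4.1445340451e+00
30.0000	4.0470003848e+00
30.2500	3.9526470856e+00
30.5000	3.8613455029e+00
30.7500	3.7729731737e+00
31.0000	3.6874134927e+00
31.2500	3.6045553641e+00
31.5000	3.5242929228e+00
31.7500	3.4465252311e+00
32.0000	3.3711560322e+00
32.2500	3.2980934780e+00
32.5000	3.2272499152e+00
32.7500	3.1585416362e+00
33.0000	3.0918887208e+00
33.2500	3.0272147866e+00
33.5000	2.9644468322e+00
33.7500	2.9035150733e+00
34.0000	2.8443527560e+00
34.2500	2.7868960212e+00
34.5000	2.7310837485e+00
34.7500	2.6768574303e+00
35.0000	2.6241610391e+00
35.2500	2.5729408954e+00
35.5000	2.5231455737e+00
35.7500	2.4747257723e+00
36.0000	2.4276342297e+00
36.2500	2.3818256092e+00
36.5000	2.3372564259e+00
36.7500	2.2938849440e+00
37.0000	2.2516711093e+00
37.2500	2.2105764557e+00
37.5000	2.1705640460e+00
37.7500	2.1315983918e+00
38.0000	2.0936453924e+00
38.2500	2.0566722684e+00
38.5000	2.0206475143e+00
38.7500	1.9855408160e+00
39.0000	1.9513230296e+00
39.2500	1.9179661061e+00
39.5000	1.8854430535e+00
39.7500	1.8537278869e+00
40.0000	1.8227955889e+00
40.2500	1.7926220654e+00
40.5000	1.7631841080e+00
40.7500	1.7344593506e+00
41.0000	1.7064262386e+00
41.2500	1.6790639995e+00
41.5000	1.6523525986e+00
41.7500	1.6262727214e+00
42.0000	1.6008057300e+00
42.2500	1.5759336468e+00
42.5000	1.5516391236e+00
42.7500	1.5279054121e+00
43.0000	1.5047163485e+00
43.2500	1.4820563218e+00
43.5000	1.4599102561e+00
43.7500	1.4382635852e+00
44.0000	1.4171022422e+00
44.2500	1.3964126264e+00
44.5000	1.3761815949e+00
44.7500	1.3563964400e+00
45.0000	1.3370448787e+00
45.2500	1.3181150268e+00
45.5000	1.2995953943e+00
45.7500	1.2814748600e+00
46.0000	1.2637426640e+00
46.2500	1.2463883960e+00
46.5000	1.2294019756e+00
46.7500	1.2127736416e+00
47.0000	1.1964939501e+00
47.2500	1.1805537465e+00
47.5000	1.1649441662e+00
47.7500	1.1496566214e+00
48.0000	1.1346827936e+00
48.2500	1.1200146154e+00
48.5000	1.1056442673e+00
48.7500	1.0915641774e+00
49.0000	1.0777669922e+00
49.2500	1.0642455924e+00
49.5000	1.0509930595e+00
49.7500	1.0380026961e+00
50.0000	1.0252679948e+00
50.2500	1.0127826440e+00
50.5000	1.0005405213e+00
50.7500	9.8853567761e-01
51.0000	9.7676234342e-01
51.2500	9.6521491572e-01
51.5000	9.5388795014e-01
51.7500	9.4277616425e-01
52.0000	9.3187442370e-01
52.2500	9.2117774010e-01
52.5000	9.1068127111e-01
52.7500	9.0038030570e-01
53.0000	8.9027026743e-01
53.2500	8.8034670935e-01
53.5000	8.7060530578e-01
53.7500	8.6104185623e-01
54.0000	8.5165226726e-01
54.2500	8.4243256656e-01
54.5000	8.3337888569e-01
54.7500	8.2448746359e-01
55.0000	8.1575463813e-01
55.2500	8.0717685186e-01
55.5000	7.9875063778e-01
55.7500	7.9047262134e-01
56.0000	7.8233952117e-01
56.2500	7.7434814057e-01
56.5000	7.6649536910e-01
56.7500	7.5877817425e-01
57.0000	7.5119360795e-01
57.2500	7.4373879691e-01
57.5000	7.3641093761e-01
57.7500	7.2920730833e-01
58.0000	7.2212524749e-01
58.2500	7.1516216732e-01
58.5000	7.0831554748e-01
58.7500	7.0158292615e-01
59.0000	6.9496190912e-01
59.2500	6.8845015835e-01
59.5000	6.8204539534e-01
59.7500	6.7574539963e-01
60.0000	6.6954800502e-01
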
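energy_keV	mu_over_rho_cm2_g
15.0000	5.4308597015e+01
15.2500	5.1952599528e+01
15.5000	4.9734412379e+01
15.7500	4.7643969467e+01
16.0000	4.5672081295e+01
16.2500	4.3810346821e+01
16.5000	4.2050910745e+01
16.7500	4.0386570874e+01
17.0000	3.8811251817e+01
17.2500	3.7318997036e+01
17.5000	3.5904286958e+01
17.7500	3.4561817152e+01
18.0000	3.3287280629e+01
18.2500	3.2076372707e+01
18.5000	3.0925115031e+01
18.7500	2.9829826748e+01
19.0000	2.8787098856e+01
19.2500	2.7793770838e+01
19.5000	2.6846909763e+01
19.7500	2.5943785098e+01
20.0000	2.5081257358e+01
20.2500	2.4257688378e+01
20.5000	2.3470869959e+01
20.7500	2.2718744074e+01
21.0000	2.1999390880e+01
21.2500	2.1310615089e+01
21.5000	2.0651175105e+01
21.7500	2.0019547301e+01
22.0000	1.9414257807e+01
22.2500	1.8833926555e+01
22.5000	1.8277234787e+01
22.7500	1.7742699142e+01
23.0000	1.7229545198e+01
23.2500	1.6736695674e+01
23.5000	1.6263137156e+01
23.7500	1.5807920559e+01
24.0000	1.5370152879e+01
24.2500	1.4948993374e+01
24.5000	1.4543649966e+01
24.7500	1.4153375981e+01
25.0000	1.3777467091e+01
25.2500	1.3415258584e+01
25.5000	1.3066122653e+01
25.7500	1.2729466124e+01
26.0000	1.2404728156e+01
26.2500	1.2091378210e+01
26.5000	1.1788914145e+01
26.7500	1.1496238263e+01
27.0000	1.1211179948e+01
27.2500	1.0935885962e+01
27.5000	1.0669935340e+01
27.7500	1.0412928932e+01
28.0000	1.0164488115e+01
28.2500	9.9242534810e+00
28.5000	9.6918838285e+00
28.7500	9.4670549636e+00
29.0000	9.2494587734e+00
29.2500	9.0388023021e+00
29.5000	8.8348068458e+00
29.7500	8.6372071533e+00
30.0000	8.4457506866e+00
30.2500	8.2601969197e+00
30.5000	8.0803166204e+00
30.7500	7.9058912691e+00
31.0000	7.7367124749e+00
31.2500	7.5725814318e+00
31.5000	7.4133083796e+00
31.6694	7.3080538370e+00
31.7194	7.2773894071e+00
31.7500	7.2587121245e+00
31.7694	7.2469059333e+00
31.8194	7.2166020554e+00
31.8694	7.1864764404e+00
31.9194	7.1565277548e+00
31.9694	7.1267546890e+00
32.0000	7.1086196234e+00
32.0194	7.0971559202e+00
32.0694	7.0677301633e+00
32.1194	7.0384761373e+00
32.1694	7.0093925674e+00
32.2194	6.9804782037e+00
32.2500	6.9628655408e+00
32.2694	6.9517317909e+00
32.3194	6.9231520836e+00
32.3694	6.8947378644e+00
32.4194	6.8664879270e+00
32.4694	6.8384010513e+00
32.5000	6.8212918187e+00
32.5194	6.8104760538e+00
32.5694	6.7827117402e+00
32.6194	6.7551069457e+00
32.6694	6.7276605055e+00
32.7194	6.7003712715e+00
32.7500	6.6837473147e+00
32.7694	6.6732380975e+00
32.8194	6.6462598512e+00
32.8694	6.6194354174e+00
32.9194	6.5927636759e+00
32.9694	6.5662435242e+00
33.0000	6.5500875060e+00
33.0194	6.5398738791e+00
33.0694	6.5136536502e+00
33.1194	6.4875817548e+00
33.1694	6.4617605514e+00
33.1694	3.5958960617e+01
33.2194	3.5819094429e+01
33.2500	3.5733523251e+01
33.2694	3.5679417736e+01
33.3194	3.5540488655e+01
33.3694	3.5402302092e+01
33.4194	3.5264853015e+01
33.4694	3.5128136420e+01
33.5000	3.5044825040e+01
33.5194	3.4992147347e+01
33.5694	3.4856880890e+01
33.6194	3.4722332166e+01
33.6694	3.4588496323e+01
33.7194	3.4455368580e+01
33.7500	3.4374241641e+01
33.7694	3.4322944179e+01
33.8194	3.4191218399e+01
33.8694	3.4060186562e+01
33.9194	3.3929844004e+01
33.9694	3.3800186148e+01
34.0000	3.3721171312e+01
34.0194	3.3671208409e+01
34.0694	3.3542906265e+01
34.1194	3.3415275215e+01
34.1694	3.3288310812e+01
34.2194	3.3162008622e+01
34.2500	3.3085036450e+01
34.2694	3.3036364264e+01
34.3194	3.2911373372e+01
34.3694	3.2787031657e+01
34.4194	3.2663334822e+01
34.4694	3.2540278621e+01
34.5000	3.2465282426e+01
34.5194	3.2417858849e+01
34.5694	3.2296071302e+01
34.6194	3.2174911853e+01
34.7500	3.1861376536e+01
35.0000	3.1274935999e+01
35.2500	3.0703633143e+01
35.5000	3.0146422828e+01
35.7500	2.9602867791e+01
36.0000	2.9072547101e+01
36.2500	2.8555055456e+01
36.5000	2.8050002557e+01
36.7500	2.7557012390e+01
37.0000	2.7075722625e+01
37.2500	2.6605784089e+01
37.5000	2.6146860138e+01
37.7500	2.5698626164e+01
38.0000	2.5260769094e+01
38.2500	2.4832986895e+01
38.5000	2.4414988130e+01
38.7500	2.4006491538e+01
39.0000	2.3607225575e+01
39.2500	2.3216928068e+01
39.5000	2.2835345792e+01
39.7500	2.2462234160e+01
40.0000	2.2097356843e+01
40.2500	2.1740485467e+01
40.5000	2.1391399274e+01
40.7500	2.1049884843e+01
41.0000	2.0715735805e+01
41.2500	2.0388752565e+01
41.5000	2.0068742047e+01
41.7500	1.9755517438e+01
42.0000	1.9448897958e+01
42.2500	1.9148708599e+01
42.5000	1.8854780002e+01
42.7500	1.8566948111e+01
43.0000	1.8285054092e+01
43.2500	1.8008700314e+01
43.5000	1.7737778662e+01
43.7500	1.7472375627e+01
44.0000	1.7212349922e+01
44.2500	1.6957564652e+01
44.5000	1.6707887080e+01
44.7500	1.6463188549e+01
45.0000	1.6223344287e+01
45.2500	1.5988233301e+01
45.5000	1.5757738218e+01
45.7500	1.5531745171e+01
46.0000	1.5310143686e+01
46.2500	1.5092826550e+01
46.5000	1.4879689692e+01
46.7500	1.4670632099e+01
47.0000	1.4465555681e+01
47.2500	1.4264365213e+01
47.5000	1.4066968181e+01
47.7500	1.3873274748e+01
48.0000	1.3683197632e+01
48.2500	1.3496652024e+01
48.5000	1.3313555512e+01
48.7500	1.3133828002e+01
49.0000	1.2957391627e+01
49.2500	1.2784170703e+01
49.5000	1.2614091641e+01
49.7500	1.2447082868e+01
50.0000	1.2283074778e+01
50.2500	1.2121999673e+01
50.5000	1.1963791687e+01
50.7500	1.1808386725e+01
51.0000	1.1655722438e+01
51.2500	1.1505738127e+01
51.5000	1.1358374738e+01
51.7500	1.1213574747e+01
52.0000	1.1071282172e+01
52.2500	1.0931442511e+01
52.5000	1.0794002658e+01
52.7500	1.0658910928e+01
53.0000	1.0526116942e+01
53.2500	1.0395571649e+01
53.5000	1.0267227242e+01
53.7500	1.0141037148e+01
54.0000	1.0016955960e+01
54.2500	9.8949394562e+00
54.5000	9.7749445020e+00
54.7500	9.6569290614e+00
55.0000	9.5408521468e+00
55.2500	9.4266737899e+00
55.5000	9.3143550191e+00
55.7500	9.2038578276e+00
56.0000	9.0951451337e+00
56.2500	8.9881807711e+00
56.5000	8.8829294502e+00
56.7500	8.7793567493e+00
57.0000	8.6774290774e+00
57.2500	8.5771136366e+00
57.5000	8.4783784337e+00
57.7500	8.3811922306e+00
58.0000	8.2855245397e+00
58.2500	8.1913455881e+00
58.5000	8.0986263063e+00
58.7500	8.0073383097e+00
59.0000	7.9174538850e+00
59.2500	7.8289459491e+00
59.5000	7.7417880603e+00
59.7500	7.6559543771e+00
60.0000	7.5714196766e+00
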
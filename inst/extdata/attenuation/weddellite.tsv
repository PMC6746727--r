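energy_keV	mu_over_rho_cm2_g
15.0000	8.3733961534e+00
15.2500	7.9918470059e+00
15.5000	7.6336323131e+00
15.7500	7.2969926966e+00
16.0000	6.9803258494e+00
16.2500	6.6821703966e+00
16.5000	6.4011916071e+00
16.7500	6.1361687842e+00
17.0000	5.8859840120e+00
17.2500	5.6496122009e+00
17.5000	5.4261085771e+00
17.7500	5.2139597009e+00
18.0000	5.0131256515e+00
18.2500	4.8228606176e+00
18.5000	4.6424771075e+00
18.7500	4.4713406844e+00
19.0000	4.3088652419e+00
19.2500	4.1545087601e+00
19.5000	4.0077694795e+00
19.7500	3.8681824480e+00
20.0000	3.7353169846e+00
20.2500	3.6087724377e+00
20.5000	3.4881762761e+00
20.7500	3.3731824569e+00
21.0000	3.2634688485e+00
21.2500	3.1587353189e+00
21.5000	3.0587019964e+00
21.7500	2.9631076977e+00
22.0000	2.8717084821e+00
22.2500	2.7842763293e+00
22.5000	2.7005979549e+00
22.7500	2.6204736925e+00
23.0000	2.5437165018e+00
23.2500	2.4701510389e+00
23.5000	2.3996128103e+00
23.7500	2.3319474023e+00
24.0000	2.2670097621e+00
24.2500	2.2046635437e+00
24.5000	2.1447805017e+00
24.7500	2.0872399378e+00
25.0000	2.0319281852e+00
25.2500	1.9787381350e+00
25.5000	1.9275687974e+00
25.7500	1.8783249016e+00
26.0000	1.8309165179e+00
26.2500	1.7852587101e+00
26.5000	1.7412712181e+00
26.7500	1.6987749294e+00
27.0000	1.6574135371e+00
27.2500	1.6175466084e+00
27.5000	1.5791070079e+00
27.7500	1.5420311909e+00
28.0000	1.5062589760e+00
28.2500	1.4717333404e+00
28.5000	1.4384002315e+00
28.7500	1.4062083826e+00
29.0000	1.3751091513e+00
29.2500	1.3450563623e+00
29.5000	1.3160061627e+00
29.7500	1.2879168853e+00
30.0000	1.2607489267e+00
30.2500	1.2344646241e+00
30.5000	1.2090281497e+00
30.7500	1.1844054032e+00
31.0000	1.1605639184e+00
31.2500	1.1374727708e+00
31.5000	1.1151024950e+00
31.7500	1.0934250003e+00
32.0000	1.0724135044e+00
32.2500	1.0520424541e+00
32.5000	1.0322874678e+00
32.7500	1.0131252619e+00
33.0000	9.9453361155e-01
33.2500	9.7649127890e-01
33.5000	9.5897796622e-01
33.7500	9.4197427446e-01
34.0000	9.2546164881e-01
34.2500	9.0942234087e-01
34.5000	8.9383936453e-01
34.7500	8.7869646355e-01
35.0000	8.6397807070e-01
35.2500	8.4966927350e-01
35.5000	8.3575578685e-01
35.7500	8.2222391700e-01
36.0000	8.0906053845e-01
36.2500	7.9625306003e-01
36.5000	7.8378940807e-01
36.7500	7.7165799452e-01
37.0000	7.5984769835e-01
37.2500	7.4834784209e-01
37.5000	7.3714817239e-01
37.7500	7.2623883943e-01
38.0000	7.1561037876e-01
38.2500	7.0525369348e-01
38.5000	6.9516004094e-01
38.7500	6.8532101062e-01
39.0000	6.7572851568e-01
39.2500	6.6637477476e-01
39.5000	6.5725229937e-01
39.7500	6.4835388204e-01
40.0000	6.3967258319e-01
40.2500	6.3120172041e-01
40.5000	6.2293485607e-01
40.7500	6.1486578892e-01
41.0000	6.0698854079e-01
41.2500	5.9929735171e-01
41.5000	5.9178666722e-01
41.7500	5.8445113116e-01
42.0000	5.7728557638e-01
42.2500	5.7028501975e-01
42.5000	5.6344465106e-01
42.7500	5.5675982837e-01
43.0000	5.5022607120e-01
43.2500	5.4383905172e-01
43.5000	5.3759459241e-01
43.7500	5.3148865629e-01
44.0000	5.2551734411e-01
44.2500	5.1967688696e-01
44.5000	5.1396364284e-01
44.7500	5.0837409069e-01
45.0000	5.0290482689e-01
45.2500	4.9755255787e-01
45.5000	4.9231410089e-01
45.7500	4.8718637423e-01
46.0000	4.8216639725e-01
46.2500	4.7725128549e-01
46.5000	4.7243824654e-01
46.7500	4.6772457600e-01
47.0000	4.6310765816e-01
47.2500	4.5858495639e-01
47.5000	4.5415401589e-01
47.7500	4.4981245755e-01
48.0000	4.4555797730e-01
48.2500	4.4138834081e-01
48.5000	4.3730138214e-01
48.7500	4.3329500445e-01
49.0000	4.2936717046e-01
49.2500	4.2551590848e-01
49.5000	4.2173930306e-01
49.7500	4.1803549912e-01
50.0000	4.1440269397e-01
50.2500	4.1083914066e-01
50.5000	4.0734314337e-01
50.7500	4.0391305416e-01
51.0000	4.0054727488e-01
51.2500	3.9724425550e-01
51.5000	3.9400248731e-01
51.7500	3.9082050820e-01
52.0000	3.8769689567e-01
52.2500	3.8463026873e-01
52.5000	3.8161928674e-01
52.7500	3.7866264452e-01
53.0000	3.7575907560e-01
53.2500	3.7290734848e-01
53.5000	3.7010626474e-01
53.7500	3.6735466193e-01
54.0000	3.6465140642e-01
54.2500	3.6199539826e-01
54.5000	3.5938556642e-01
54.7500	3.5682086925e-01
55.0000	3.5430029280e-01
55.2500	3.5182285192e-01
55.5000	3.4938758691e-01
55.7500	3.4699356323e-01
56.0000	3.4463987206e-01
56.2500	3.4232562858e-01
56.5000	3.4004997076e-01
56.7500	3.3781205990e-01
57.0000	3.3561107925e-01
57.2500	3.3344623287e-01
57.5000	3.3131674490e-01
57.7500	3.2922186102e-01
58.0000	3.2716084505e-01
58.2500	3.2513297999e-01
58.5000	3.2313756732e-01
58.7500	3.2117392645e-01
59.0000	3.1924139318e-01
59.2500	3.1733932088e-01
59.5000	3.1546707792e-01
59.7500	3.1362404986e-01
60.0000	3.1180963654e-01
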
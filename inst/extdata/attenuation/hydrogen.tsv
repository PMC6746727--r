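energy_keV	mu_over_rho_cm2_g
15.0000	3.7582543148e-01
15.2500	3.7548754802e-01
15.5000	3.7515060815e-01
15.7500	3.7481459855e-01
16.0000	3.7447950674e-01
16.2500	3.7414532109e-01
16.5000	3.7381203066e-01
16.7500	3.7347962520e-01
17.0000	3.7314809503e-01
17.2500	3.7281743104e-01
17.5000	3.7248762463e-01
17.7500	3.7215866764e-01
18.0000	3.7183055235e-01
18.2500	3.7150327139e-01
18.5000	3.7117681777e-01
18.7500	3.7085118482e-01
19.0000	3.7052636617e-01
19.2500	3.7020235571e-01
19.5000	3.6987914759e-01
19.7500	3.6955673620e-01
20.0000	3.6923511613e-01
20.2500	3.6891428219e-01
20.5000	3.6859422935e-01
20.7500	3.6827495279e-01
21.0000	3.6795644780e-01
21.2500	3.6763870987e-01
21.5000	3.6732173458e-01
21.7500	3.6700551767e-01
22.0000	3.6669005500e-01
22.2500	3.6637534252e-01
22.5000	3.6606137631e-01
22.7500	3.6574815253e-01
23.0000	3.6543566745e-01
23.2500	3.6512391741e-01
23.5000	3.6481289884e-01
23.7500	3.6450260825e-01
24.0000	3.6419304221e-01
24.2500	3.6388419738e-01
24.5000	3.6357607046e-01
24.7500	3.6326865822e-01
25.0000	3.6296195749e-01
25.2500	3.6265596516e-01
25.5000	3.6235067816e-01
25.7500	3.6204609347e-01
26.0000	3.6174220812e-01
26.2500	3.6143901919e-01
26.5000	3.6113652380e-01
26.7500	3.6083471909e-01
27.0000	3.6053360227e-01
27.2500	3.6023317057e-01
27.5000	3.5993342125e-01
27.7500	3.5963435161e-01
28.0000	3.5933595898e-01
28.2500	3.5903824073e-01
28.5000	3.5874119424e-01
28.7500	3.5844481694e-01
29.0000	3.5814910628e-01
29.2500	3.5785405972e-01
29.5000	3.5755967476e-01
29.7500	3.5726594893e-01
30.0000	3.5697287977e-01
30.2500	3.5668046485e-01
30.5000	3.5638870176e-01
30.7500	3.5609758811e-01
31.0000	3.5580712154e-01
31.2500	3.5551729968e-01
31.5000	3.5522812023e-01
31.7500	3.5493958085e-01
32.0000	3.5465167926e-01
32.2500	3.5436441319e-01
32.5000	3.5407778037e-01
32.7500	3.5379177857e-01
33.0000	3.5350640556e-01
33.2500	3.5322165913e-01
33.5000	3.5293753708e-01
33.7500	3.5265403724e-01
34.0000	3.5237115744e-01
34.2500	3.5208889553e-01
34.5000	3.5180724938e-01
34.7500	3.5152621686e-01
35.0000	3.5124579586e-01
35.2500	3.5096598429e-01
35.5000	3.5068678006e-01
35.7500	3.5040818111e-01
36.0000	3.5013018537e-01
36.2500	3.4985279080e-01
36.5000	3.4957599536e-01
36.7500	3.4929979704e-01
37.0000	3.4902419382e-01
37.2500	3.4874918370e-01
37.5000	3.4847476470e-01
37.7500	3.4820093483e-01
38.0000	3.4792769213e-01
38.2500	3.4765503465e-01
38.5000	3.4738296043e-01
38.7500	3.4711146755e-01
39.0000	3.4684055407e-01
39.2500	3.4657021809e-01
39.5000	3.4630045770e-01
39.7500	3.4603127100e-01
40.0000	3.4576265610e-01
40.2500	3.4549461113e-01
40.5000	3.4522713423e-01
40.7500	3.4496022353e-01
41.0000	3.4469387719e-01
41.2500	3.4442809337e-01
41.5000	3.4416287023e-01
41.7500	3.4389820596e-01
42.0000	3.4363409875e-01
42.2500	3.4337054678e-01
42.5000	3.4310754826e-01
42.7500	3.4284510141e-01
43.0000	3.4258320445e-01
43.2500	3.4232185560e-01
43.5000	3.4206105311e-01
43.7500	3.4180079522e-01
44.0000	3.4154108019e-01
44.2500	3.4128190627e-01
44.5000	3.4102327174e-01
44.7500	3.4076517487e-01
45.0000	3.4050761396e-01
45.2500	3.4025058729e-01
45.5000	3.3999409316e-01
45.7500	3.3973812988e-01
46.0000	3.3948269578e-01
46.2500	3.3922778917e-01
46.5000	3.3897340839e-01
46.7500	3.3871955176e-01
47.0000	3.3846621765e-01
47.2500	3.3821340440e-01
47.5000	3.3796111037e-01
47.7500	3.3770933393e-01
48.0000	3.3745807345e-01
48.2500	3.3720732732e-01
48.5000	3.3695709392e-01
48.7500	3.3670737164e-01
49.0000	3.3645815890e-01
49.2500	3.3620945410e-01
49.5000	3.3596125565e-01
49.7500	3.3571356198e-01
50.0000	3.3546637152e-01
50.2500	3.3521968270e-01
50.5000	3.3497349396e-01
50.7500	3.3472780376e-01
51.0000	3.3448261054e-01
51.2500	3.3423791278e-01
51.5000	3.3399370893e-01
51.7500	3.3374999748e-01
52.0000	3.3350677691e-01
52.2500	3.3326404569e-01
52.5000	3.3302180233e-01
52.7500	3.3278004533e-01
53.0000	3.3253877319e-01
53.2500	3.3229798442e-01
53.5000	3.3205767755e-01
53.7500	3.3181785109e-01
54.0000	3.3157850357e-01
54.2500	3.3133963354e-01
54.5000	3.3110123954e-01
54.7500	3.3086332010e-01
55.0000	3.3062587380e-01
55.2500	3.3038889918e-01
55.5000	3.3015239482e-01
55.7500	3.2991635928e-01
56.0000	3.2968079114e-01
56.2500	3.2944568899e-01
56.5000	3.2921105142e-01
56.7500	3.2897687701e-01
57.0000	3.2874316437e-01
57.2500	3.2850991211e-01
57.5000	3.2827711883e-01
57.7500	3.2804478315e-01
58.0000	3.2781290370e-01
58.2500	3.2758147911e-01
58.5000	3.2735050800e-01
58.7500	3.2711998901e-01
59.0000	3.2688992080e-01
59.2500	3.2666030200e-01
59.5000	3.2643113128e-01
59.7500	3.2620240729e-01
60.0000	3.2597412870e-01
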
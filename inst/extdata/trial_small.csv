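# synthetic crossover trial: generate_trial(trial_design(n_subjects = 6), mbpk_params(), seed = 101)
ID,TIME,AMT,DV,EVID,MDV,OCC,FOOD,CAL
1,0,250,0,1,1,1,0,0
1,0,0,0,0,1,1,0,0
1,1,0,0.02102277,0,0,1,0,0
1,2,0,0.01742111,0,0,1,0,0
1,3,0,0.1002137,0,0,1,0,0
1,4,0,0.2297082,0,0,1,0,0
1,5,0,0.3077312,0,0,1,0,0
1,6,0,0.1620274,0,0,1,0,0
1,8,0,0.2374977,0,0,1,0,0
1,10,0,0.04594221,0,0,1,0,0
1,12,0,0.2113487,0,0,1,0,0
1,24,0,0.3192068,0,0,1,0,0
1,48,0,0.1614715,0,0,1,0,0
1,72,0,0.06511649,0,0,1,0,0
1,240,250,0,1,1,2,1,686.3
1,240,0,0,0,1,2,1,0
1,241,0,0.01587094,0,0,2,1,0
1,242,0,0.1029395,0,0,2,1,0
1,243,0,0.1774545,0,0,2,1,0
1,244,0,0.2704537,0,0,2,1,0
1,245,0,0.7366206,0,0,2,1,0
1,246,0,0.9531604,0,0,2,1,0
1,248,0,1.085147,0,0,2,1,0
1,250,0,0.6856503,0,0,2,1,0
1,252,0,0.8118529,0,0,2,1,0
1,264,0,0.2124115,0,0,2,1,0
1,288,0,0.2806,0,0,2,1,0
1,312,0,0.0215578,0,0,2,1,0
1,480,250,0,1,1,3,2,1280
1,480,0,0,0,1,3,2,0
1,481,0,0.1027976,0,0,3,2,0
1,482,0,0.7250695,0,0,3,2,0
1,483,0,1.039037,0,0,3,2,0
1,484,0,0.6168805,0,0,3,2,0
1,485,0,0.764262,0,0,3,2,0
1,486,0,1.3207,0,0,3,2,0
1,488,0,2.066353,0,0,3,2,0
1,490,0,1.62521,0,0,3,2,0
1,492,0,2.789738,0,0,3,2,0
1,504,0,1.341296,0,0,3,2,0
1,528,0,0.7213403,0,0,3,2,0
1,552,0,0.2726361,0,0,3,2,0
2,0,250,0,1,1,1,0,0
2,0,0,0,0,1,1,0,0
2,1,0,0.1887353,0,0,1,0,0
2,2,0,0.4498994,0,0,1,0,0
2,3,0,1.751516,0,0,1,0,0
2,4,0,1.15015,0,0,1,0,0
2,5,0,2.110269,0,0,1,0,0
2,6,0,6.394245,0,0,1,0,0
2,8,0,5.75076,0,0,1,0,0
2,10,0,2.508219,0,0,1,0,0
2,12,0,6.068423,0,0,1,0,0
2,24,0,2.543812,0,0,1,0,0
2,48,0,2.976651,0,0,1,0,0
2,72,0,0.6844891,0,0,1,0,0
2,240,250,0,1,1,2,1,686.3
2,240,0,0,0,1,2,1,0
2,241,0,0.9498799,0,0,2,1,0
2,242,0,1.910118,0,0,2,1,0
2,243,0,4.479629,0,0,2,1,0
2,244,0,3.969336,0,0,2,1,0
2,245,0,6.141134,0,0,2,1,0
2,246,0,21.32713,0,0,2,1,0
2,248,0,8.840007,0,0,2,1,0
2,250,0,14.2946,0,0,2,1,0
2,252,0,13.39274,0,0,2,1,0
2,264,0,18.76975,0,0,2,1,0
2,288,0,4.247405,0,0,2,1,0
2,312,0,0.4694497,0,0,2,1,0
2,480,250,0,1,1,3,2,1280
2,480,0,0,0,1,3,2,0
2,481,0,0.3260067,0,0,3,2,0
2,482,0,1.47845,0,0,3,2,0
2,483,0,7.268038,0,0,3,2,0
2,484,0,4.24268,0,0,3,2,0
2,485,0,5.160346,0,0,3,2,0
2,486,0,2.993518,0,0,3,2,0
2,488,0,11.27882,0,0,3,2,0
2,490,0,24.46092,0,0,3,2,0
2,492,0,10.97289,0,0,3,2,0
2,504,0,9.207236,0,0,3,2,0
2,528,0,4.862168,0,0,3,2,0
2,552,0,3.70448,0,0,3,2,0
3,0,250,0,1,1,1,0,0
3,0,0,0,0,1,1,0,0
3,1,0,0.09655495,0,0,1,0,0
3,2,0,0.6193436,0,0,1,0,0
3,3,0,0.8291591,0,0,1,0,0
3,4,0,0.02713813,0,0,1,0,0
3,5,0,2.377621,0,0,1,0,0
3,6,0,0.2433771,0,0,1,0,0
3,8,0,4.16925,0,0,1,0,0
3,10,0,4.590122,0,0,1,0,0
3,12,0,4.154998,0,0,1,0,0
3,24,0,1.328459,0,0,1,0,0
3,48,0,0.3562572,0,0,1,0,0
3,72,0,0.2850377,0,0,1,0,0
3,240,250,0,1,1,2,1,686.3
3,240,0,0,0,1,2,1,0
3,241,0,0.2518082,0,0,2,1,0
3,242,0,1.041322,0,0,2,1,0
3,243,0,1.145473,0,0,2,1,0
3,244,0,2.653773,0,0,2,1,0
3,245,0,1.932587,0,0,2,1,0
3,246,0,2.800821,0,0,2,1,0
3,248,0,2.979368,0,0,2,1,0
3,250,0,2.696448,0,0,2,1,0
3,252,0,4.899468,0,0,2,1,0
3,264,0,1.536619,0,0,2,1,0
3,288,0,1.800896,0,0,2,1,0
3,312,0,0.4218434,0,0,2,1,0
3,480,250,0,1,1,3,2,1280
3,480,0,0,0,1,3,2,0
3,481,0,0.06792606,0,0,3,2,0
3,482,0,1.162105,0,0,3,2,0
3,483,0,3.545615,0,0,3,2,0
3,484,0,1.763362,0,0,3,2,0
3,485,0,2.961772,0,0,3,2,0
3,486,0,2.996579,0,0,3,2,0
3,488,0,4.059486,0,0,3,2,0
3,490,0,0.2667651,0,0,3,2,0
3,492,0,0.1007721,0,0,3,2,0
3,504,0,0.7754044,0,0,3,2,0
3,528,0,1.151185,0,0,3,2,0
3,552,0,0.1837586,0,0,3,2,0
4,0,250,0,1,1,1,0,0
4,0,0,0,0,1,1,0,0
4,1,0,0.07091645,0,0,1,0,0
4,2,0,0.3808064,0,0,1,0,0
4,3,0,0.6054228,0,0,1,0,0
4,4,0,0.5377502,0,0,1,0,0
4,5,0,1.415499,0,0,1,0,0
4,6,0,1.952344,0,0,1,0,0
4,8,0,2.038691,0,0,1,0,0
4,10,0,3.421246,0,0,1,0,0
4,12,0,2.143286,0,0,1,0,0
4,24,0,1.950495,0,0,1,0,0
4,48,0,1.352478,0,0,1,0,0
4,72,0,0.1123757,0,0,1,0,0
4,240,250,0,1,1,2,1,686.3
4,240,0,0,0,1,2,1,0
4,241,0,0.07250997,0,0,2,1,0
4,242,0,0.6047721,0,0,2,1,0
4,243,0,1.427502,0,0,2,1,0
4,244,0,2.111196,0,0,2,1,0
4,245,0,0.9832698,0,0,2,1,0
4,246,0,2.256849,0,0,2,1,0
4,248,0,2.774842,0,0,2,1,0
4,250,0,2.967178,0,0,2,1,0
4,252,0,6.819686,0,0,2,1,0
4,264,0,2.317361,0,0,2,1,0
4,288,0,0.9159381,0,0,2,1,0
4,312,0,0.4534718,0,0,2,1,0
4,480,250,0,1,1,3,2,1280
4,480,0,0,0,1,3,2,0
4,481,0,0.4440745,0,0,3,2,0
4,482,0,0.5690713,0,0,3,2,0
4,483,0,2.275717,0,0,3,2,0
4,484,0,1.917708,0,0,3,2,0
4,485,0,9.897921,0,0,3,2,0
4,486,0,3.682548,0,0,3,2,0
4,488,0,6.727676,0,0,3,2,0
4,490,0,6.525241,0,0,3,2,0
4,492,0,1.131909,0,0,3,2,0
4,504,0,5.499064,0,0,3,2,0
4,528,0,0.7626017,0,0,3,2,0
4,552,0,0.8753807,0,0,3,2,0
5,0,250,0,1,1,1,0,0
5,0,0,0,0,1,1,0,0
5,1,0,0.2586369,0,0,1,0,0
5,2,0,0.4797886,0,0,1,0,0
5,3,0,1.050547,0,0,1,0,0
5,4,0,1.388079,0,0,1,0,0
5,5,0,1.388774,0,0,1,0,0
5,6,0,3.427148,0,0,1,0,0
5,8,0,1.981221,0,0,1,0,0
5,10,0,3.032506,0,0,1,0,0
5,12,0,2.308612,0,0,1,0,0
5,24,0,2.868889,0,0,1,0,0
5,48,0,0.7974626,0,0,1,0,0
5,72,0,0.2269097,0,0,1,0,0
5,240,250,0,1,1,2,1,686.3
5,240,0,0,0,1,2,1,0
5,241,0,1.089267,0,0,2,1,0
5,242,0,4.770964,0,0,2,1,0
5,243,0,8.472535,0,0,2,1,0
5,244,0,7.901695,0,0,2,1,0
5,245,0,7.889059,0,0,2,1,0
5,246,0,14.67776,0,0,2,1,0
5,248,0,7.858503,0,0,2,1,0
5,250,0,8.443578,0,0,2,1,0
5,252,0,18.07407,0,0,2,1,0
5,264,0,5.989981,0,0,2,1,0
5,288,0,2.535818,0,0,2,1,0
5,312,0,0.4270793,0,0,2,1,0
5,480,250,0,1,1,3,2,1280
5,480,0,0,0,1,3,2,0
5,481,0,1.122704,0,0,3,2,0
5,482,0,3.412502,0,0,3,2,0
5,483,0,2.261869,0,0,3,2,0
5,484,0,9.222705,0,0,3,2,0
5,485,0,8.874139,0,0,3,2,0
5,486,0,5.313829,0,0,3,2,0
5,488,0,10.14165,0,0,3,2,0
5,490,0,5.235287,0,0,3,2,0
5,492,0,11.52326,0,0,3,2,0
5,504,0,3.305117,0,0,3,2,0
5,528,0,1.685058,0,0,3,2,0
5,552,0,0.2729855,0,0,3,2,0
6,0,250,0,1,1,1,0,0
6,0,0,0,0,1,1,0,0
6,1,0,0.0316325,0,0,1,0,0
6,2,0,0.4688798,0,0,1,0,0
6,3,0,0.7997402,0,0,1,0,0
6,4,0,0.7970406,0,0,1,0,0
6,5,0,0.2162933,0,0,1,0,0
6,6,0,2.494426,0,0,1,0,0
6,8,0,4.804246,0,0,1,0,0
6,10,0,2.36776,0,0,1,0,0
6,12,0,4.761541,0,0,1,0,0
6,24,0,6.115082,0,0,1,0,0
6,48,0,7.154129,0,0,1,0,0
6,72,0,1.541105,0,0,1,0,0
6,240,250,0,1,1,2,1,686.3
6,240,0,0,0,1,2,1,0
6,241,0,0.0677036,0,0,2,1,0
6,242,0,0.5828907,0,0,2,1,0
6,243,0,1.739466,0,0,2,1,0
6,244,0,0.6410995,0,0,2,1,0
6,245,0,2.077194,0,0,2,1,0
6,246,0,2.296845,0,0,2,1,0
6,248,0,0.572501,0,0,2,1,0
6,250,0,7.219217,0,0,2,1,0
6,252,0,2.377048,0,0,2,1,0
6,264,0,4.822727,0,0,2,1,0
6,288,0,0.7203807,0,0,2,1,0
6,312,0,0.1286795,0,0,2,1,0
6,480,250,0,1,1,3,2,1280
6,480,0,0,0,1,3,2,0
6,481,0,0.5759167,0,0,3,2,0
6,482,0,2.435362,0,0,3,2,0
6,483,0,1.325036,0,0,3,2,0
6,484,0,9.335056,0,0,3,2,0
6,485,0,8.648423,0,0,3,2,0
6,486,0,5.007829,0,0,3,2,0
6,488,0,18.92728,0,0,3,2,0
6,490,0,5.3823,0,0,3,2,0
6,492,0,21.54616,0,0,3,2,0
6,504,0,18.96747,0,0,3,2,0
6,528,0,2.02293,0,0,3,2,0
6,552,0,1.396038,0,0,3,2,0
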
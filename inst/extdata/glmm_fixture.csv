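farm_id,semester,x1,x2,denominator,numerator
f02,s1,0.449359,1.575536,40,8
f05,s2,-0.108154,0.679106,40,6
f13,s4,0.715474,-0.682007,40,27
f17,s2,0.179835,-0.378694,40,8
f13,s4,1.318584,0.033698,40,24
f09,s3,0.389645,0.72052,40,19
f02,s1,-1.335167,0.405401,40,2
f11,s2,-1.609584,0.436069,40,17
f16,s1,-0.869807,-0.207032,40,6
f14,s1,2.930535,-0.213478,40,25
f02,s2,-0.42158,0.240989,40,3
f12,s2,-0.03983,-1.699139,40,16
f18,s1,0.038127,1.528029,40,14
f01,s2,1.042561,-0.297904,40,10
f11,s3,-0.641328,0.517325,40,19
f03,s4,-1.068466,1.342459,40,4
f09,s4,0.199851,1.963914,40,6
f14,s3,0.388162,-0.632991,40,11
f17,s1,-0.679451,-0.102619,40,7
f16,s4,2.657171,-1.669625,40,33
f20,s4,-0.163251,0.257891,40,5
f20,s3,-1.024364,-0.083052,40,4
f11,s4,0.685924,0.523761,40,33
f20,s4,-1.952814,0.172416,40,1
f20,s4,-0.364626,-1.853931,40,8
f10,s3,0.083702,-0.998641,40,9
f04,s3,-0.624971,-0.953631,40,11
f07,s1,1.338425,0.810818,40,10
f20,s4,-0.478238,-1.473227,40,9
f16,s2,1.131239,0.824267,40,8
f20,s2,-1.515023,1.533194,40,0
f03,s1,1.370302,-0.567801,40,22
f02,s4,-2.075155,-0.170632,40,3
f17,s4,0.008655,1.141836,40,6
f17,s3,0.442947,-1.439273,40,15
f03,s1,-0.653474,-1.221525,40,15
f01,s1,-1.590859,0.832088,40,2
f06,s1,0.327439,-1.856959,40,24
f20,s4,0.035218,-0.895814,40,6
f09,s2,0.724555,0.79073,40,12
f15,s3,1.513075,0.173656,40,28
f13,s4,-1.150594,0.137665,40,10
f16,s3,0.478889,-0.971846,40,15
f11,s1,-1.145499,1.810939,40,15
f02,s1,1.296579,1.488164,40,5
f17,s3,-0.408942,0.011825,40,4
f19,s4,0.796493,-1.233548,40,18
f12,s4,0.722923,-1.360662,40,32
f05,s2,-0.757971,0.483102,40,5
f16,s2,-2.03991,-0.276536,40,2
f06,s4,-0.508886,-0.315055,40,10
f03,s2,0.729137,-0.336186,40,14
f01,s4,0.815266,1.48749,40,8
f11,s3,1.174676,0.513054,40,36
f19,s1,-1.102577,-0.307497,40,6
f09,s1,-0.245348,-2.582683,40,23
f03,s4,0.549979,1.288737,40,7
f11,s3,-0.749337,0.60376,40,16
f20,s3,-0.652114,0.130201,40,5
f14,s3,0.441817,0.216207,40,6
f16,s4,-0.529122,-0.836788,40,8
f04,s2,0.171338,-0.112216,40,15
f14,s1,0.116515,-2.096616,40,13
f17,s2,0.590537,-0.086619,40,11
f08,s3,-0.710853,-0.494724,40,22
f09,s4,1.744102,-1.241386,40,29
f20,s2,-0.424726,1.195298,40,6
f16,s3,-0.412485,-0.652173,40,8
f18,s3,-0.149245,1.593966,40,4
f11,s2,0.049048,0.479017,40,27
f02,s3,-0.129924,-0.86523,40,7
f19,s1,-0.208862,0.882854,40,5
f12,s4,-0.462897,2.270658,40,11
f17,s4,2.325431,0.04999,40,27
f02,s4,-0.842429,0.142794,40,5
f09,s3,0.173924,0.81574,40,5
f16,s4,-0.244684,-1.073645,40,14
f13,s3,0.264457,-0.34067,40,19
f06,s3,0.030958,-0.738891,40,23
f04,s3,1.527731,-0.198861,40,17
f17,s2,0.390436,0.880889,40,5
f15,s4,-1.614945,-0.280877,40,14
f16,s2,0.821067,-1.153606,40,17
f13,s4,-0.13237,-0.159046,40,25
f07,s1,1.206132,-0.159645,40,18
f03,s4,0.014338,-1.377905,40,15
f04,s3,0.743466,-1.003738,40,16
f07,s2,0.893714,-1.685866,40,13
f11,s2,-1.143852,-0.331495,40,17
f14,s4,1.418373,-0.806465,40,19
f11,s2,0.551936,1.232147,40,29
f09,s2,-0.414305,-1.106464,40,8
f15,s4,-0.159779,0.697909,40,15
f02,s4,-1.351135,0.183561,40,1
f08,s2,-0.183078,1.406968,40,14
f10,s3,2.000434,-0.783154,40,18
f19,s1,0.788404,-0.502735,40,16
f02,s1,0.189904,0.699978,40,5
f17,s4,-0.829426,0.760986,40,4
f14,s4,0.957955,0.192498,40,11
f02,s4,-2.060187,-1.300892,40,1
f11,s2,0.24621,-0.939301,40,31
f01,s4,-0.104772,2.007886,40,1
f02,s1,0.322336,-0.492177,40,11
f03,s1,0.704925,-2.042061,40,31
f13,s2,1.397902,0.984148,40,19
f05,s4,0.076641,-0.835142,40,11
f05,s3,0.82024,-0.410276,40,7
f02,s2,0.732567,-0.276644,40,7
f17,s1,0.739527,0.553683,40,16
f04,s1,0.076543,1.087035,40,14
f16,s2,-1.080164,-0.651572,40,4
f09,s2,-0.804432,-0.31509,40,6
f18,s3,-1.559609,-0.186946,40,6
f02,s4,0.61052,0.026871,40,10
f13,s1,-1.717373,0.58962,40,12
f10,s4,1.575181,-0.573135,40,18
f01,s1,-0.101878,0.148739,40,12
f19,s2,-0.432578,0.851799,40,2
f01,s4,0.852833,-1.682939,40,13
f18,s2,-0.292771,0.519368,40,10
f01,s1,1.459605,-0.718608,40,23
f08,s1,-1.384445,0.853879,40,14
f08,s3,0.805431,-0.062331,40,25
f16,s4,1.415627,-0.402194,40,19
f10,s3,2.098684,0.499308,40,16
f05,s2,1.444875,-0.134943,40,15
f05,s2,0.980797,-0.264779,40,7
f11,s4,-0.916227,-0.763837,40,28
f07,s3,0.991682,-0.427377,40,14
f01,s3,0.988164,-0.89886,40,18
f03,s4,-1.629609,-0.034751,40,2
f14,s1,-0.893656,-0.055548,40,11
f09,s4,-0.591254,0.586792,40,14
f04,s1,-0.013148,-1.400817,40,24
f12,s1,-0.615715,-0.13022,40,22
f04,s4,1.562094,0.504924,40,22
f19,s3,-0.214986,0.298694,40,3
f03,s3,-0.445027,2.925858,40,3
f05,s1,0.559883,0.568355,40,15
f17,s4,-0.400321,-0.233408,40,7
f14,s2,-1.224994,0.647928,40,2
f05,s2,-0.523081,0.039401,40,7
f08,s1,0.188607,-0.56634,40,27
f08,s3,-0.409421,-1.169568,40,14
f17,s2,-1.127335,-0.338212,40,5
f13,s1,0.892484,-0.25119,40,28
f06,s3,-0.856545,0.826726,40,4
f01,s1,-2.265425,0.990471,40,2
f12,s2,0.766372,0.776481,40,10
f09,s2,0.962877,-0.805946,40,22
f10,s1,0.469298,-0.401496,40,13
f07,s4,0.737285,1.686695,40,8
f01,s4,-1.209526,1.748606,40,2
f09,s3,1.231078,-1.57979,40,25
f12,s1,0.653685,-0.960991,40,30
f18,s3,0.63541,1.168111,40,19
f19,s4,0.537717,-0.169963,40,12
f20,s3,1.180191,-0.980896,40,15
f17,s3,-1.571286,-0.522697,40,4
f01,s2,-0.043193,-1.042827,40,10
f19,s3,0.136977,-0.027249,40,13
f05,s1,1.297325,-0.562574,40,24
f05,s2,1.850766,0.541148,40,25
f15,s2,-0.586205,0.5964,40,13
f09,s3,0.773647,-0.502626,40,21
f01,s3,-0.208377,-0.457652,40,5
f13,s2,-0.315286,0.120304,40,16
f20,s1,-0.040975,0.35265,40,4
f12,s1,-0.215492,1.624056,40,10
f12,s4,-0.037107,-0.364399,40,21
f07,s2,-0.060824,-0.191191,40,5
f10,s1,-0.736172,1.800086,40,0
f11,s2,-0.54194,0.537693,40,18
f19,s1,0.658679,0.224131,40,15
f11,s4,0.305999,0.859988,40,24
f02,s4,-0.600645,-1.131548,40,11
f16,s4,-0.694508,-0.59413,40,8
f05,s4,0.58556,-0.028001,40,17
f20,s3,-0.891065,-0.911622,40,1
f07,s4,0.347957,0.968812,40,7
f10,s4,-0.232462,0.808183,40,4
f19,s4,0.235008,1.076996,40,9
f14,s3,-0.491388,0.876674,40,6
f12,s2,0.998426,-0.13154,40,22
f16,s1,-0.020213,-1.02131,40,15
f01,s3,-0.133716,1.068718,40,1
f11,s4,0.386303,-1.338976,40,35
f11,s4,-0.204947,0.110171,40,26
f04,s1,-0.851459,-1.63057,40,12
f18,s2,0.144652,-0.36187,40,19
f09,s3,-0.596432,1.081172,40,7
f19,s2,0.946758,0.416293,40,10
f02,s2,-1.520735,1.694832,40,1
f08,s4,0.554728,-1.209561,40,30
f07,s3,0.775253,-0.13395,40,9
f07,s1,-0.731188,-1.307748,40,9
f01,s3,0.799038,0.843191,40,6
f18,s2,0.015869,-0.639968,40,16
f14,s3,2.233508,-1.259079,40,20
f07,s1,-0.828033,0.081782,40,11
f20,s1,-2.090042,-0.193424,40,1
f15,s3,1.766027,-0.336656,40,29
f12,s3,-0.081391,1.040915,40,12
f03,s3,-1.075391,-0.410447,40,5
f18,s4,0.072311,-0.217606,40,20
f15,s1,0.445265,0.636158,40,25
f04,s4,-0.935341,1.928073,40,4
f15,s2,0.888977,-0.031687,40,18
f17,s4,-0.564471,1.10547,40,4
f20,s2,-0.844781,-0.401392,40,3
f16,s3,-0.673842,-0.098076,40,7
f03,s2,-0.383762,0.161802,40,5
f11,s1,-0.230273,-1.195776,40,33
f14,s2,-2.121709,2.363357,40,1
f08,s1,-0.806556,-0.993587,40,19
f01,s1,-0.452892,-0.153084,40,8
f19,s3,-0.765607,-1.82357,40,7
f03,s1,-1.962237,-0.206096,40,5
f16,s1,-0.368125,-1.941151,40,14
f16,s4,1.685,-0.794527,40,23
f18,s3,-1.137521,-0.36391,40,13
f12,s4,0.787271,0.268547,40,21
f01,s2,0.731025,-2.916337,40,22
f12,s3,0.332517,-0.270859,40,20
f13,s3,-0.854752,-0.479129,40,11
f11,s3,-1.16031,0.74167,40,19
f07,s1,-0.247653,-0.409799,40,8
f01,s3,0.630009,-0.021122,40,9
f05,s3,0.229049,-0.355432,40,10
f19,s4,2.02784,0.877033,40,17
f02,s3,-0.147418,-1.192127,40,3
f15,s2,-0.840491,-1.089478,40,11
f19,s1,-1.832969,0.510292,40,9
f15,s3,0.163806,0.706248,40,9
f04,s2,-1.121995,0.148309,40,2
f10,s1,-0.48637,1.385585,40,6
f14,s2,0.32988,-0.167896,40,14
f15,s1,-1.07732,-0.563909,40,18
f06,s3,-0.393928,0.267092,40,6
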
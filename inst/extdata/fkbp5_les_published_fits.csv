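outcome,moderator,n,b0,b1,b2,b3,adj_r_squared,p_interaction,slope_risk,slope_risk_ci_lower,slope_risk_ci_upper,slope_risk_p,ros_lower,ros_upper,poi,pa,crossover
depressive_symptoms,rs3800373,86,7.455,-2.019,-0.795,-0.730,0.132,0.590,NA,NA,NA,NA,NA,NA,NA,NA,NA
depressive_symptoms,rs9296158,86,7.489,-1.980,-0.739,-1.035,0.138,0.438,NA,NA,NA,NA,NA,NA,NA,NA,NA
depressive_symptoms,rs1360780,86,6.541,-1.689,1.098,-1.791,0.140,0.177,NA,NA,NA,NA,NA,NA,NA,NA,NA
depressive_symptoms,rs9470080,86,8.088,-2.792,-1.898,0.571,0.138,0.670,NA,NA,NA,NA,NA,NA,NA,NA,NA
depressive_symptoms,rs4713916,86,7.583,-2.595,-1.124,0.599,0.128,0.964,NA,NA,NA,NA,NA,NA,NA,NA,NA
depressive_symptoms,HAPL,83,7.436,-2.046,-0.366,-1.212,0.139,0.387,NA,NA,NA,NA,NA,NA,NA,NA,NA
state_anxiety,rs3800373,86,5.857,-0.394,1.186,-1.898,0.048,0.142,NA,NA,NA,NA,NA,NA,NA,NA,NA
state_anxiety,rs9296158,86,5.756,-0.449,1.476,-2.148,0.057,0.092,NA,NA,NA,NA,NA,NA,NA,NA,NA
state_anxiety,rs1360780,86,5.298,-0.383,2.126,-2.221,0.065,0.078,NA,NA,NA,NA,NA,NA,NA,NA,NA
state_anxiety,rs9470080,86,5.663,-0.944,1.189,-0.869,0.032,0.500,NA,NA,NA,NA,NA,NA,NA,NA,NA
state_anxiety,rs4713916,86,5.482,-0.815,1.671,-1.306,0.042,0.305,NA,NA,NA,NA,NA,NA,NA,NA,NA
state_anxiety,HAPL,83,5.825,-0.656,1.603,-2.215,0.069,0.096,NA,NA,NA,NA,NA,NA,NA,NA,NA
neuroticism,rs3800373,86,76.944,0.013,4.113,-12.464,0.102,0.024,-12.45,-19.72,-5.19,0.001,-2.076,1.555,0.62,0.37,0.330
neuroticism,rs9296158,86,75.930,-1.153,6.626,-12.819,0.104,0.019,-13.97,-21.81,-6.13,0.001,-1.045,1.867,0.52,0.30,0.517
neuroticism,rs1360780,86,73.990,-1.939,8.926,-10.909,0.091,0.044,-12.85,-20.53,-5.17,0.001,-0.878,11.613,0.37,0.21,0.818
neuroticism,rs9470080,86,77.990,-5.759,0.402,-2.163,0.043,0.697,NA,NA,NA,NA,NA,NA,NA,NA,NA
neuroticism,rs4713916,86,77.971,-5.463,0.383,-3.729,0.048,0.499,NA,NA,NA,NA,NA,NA,NA,NA,NA
neuroticism,HAPL,83,76.514,-2.724,7.405,-12.651,0.123,0.024,-15.38,-23.60,-7.15,0.001,-1.025,2.287,0.49,0.28,0.585
social_anxiety,rs3800373,86,20.849,-0.204,5.106,-6.037,0.107,0.021,-6.24,-9.67,-2.81,0.001,0.358,9.59,0.18,0.10,1.278
social_anxiety,rs9296158,86,20.243,-0.951,6.315,-5.610,0.111,0.029,-6.56,-10.26,-2.87,0.001,0.190,6.505,0.24,0.13,1.126
social_anxiety,rs1360780,86,19.428,-1.459,6.918,-4.179,0.108,0.099,NA,NA,NA,NA,NA,NA,NA,NA,NA
social_anxiety,rs9470080,86,20.197,-0.961,5.092,-4.293,0.085,0.098,NA,NA,NA,NA,NA,NA,NA,NA,NA
social_anxiety,rs4713916,86,20.843,-2.171,4.216,-2.415,0.065,0.352,NA,NA,NA,NA,NA,NA,NA,NA,NA
social_anxiety,HAPL,83,20.689,-0.630,6.213,-5.896,0.098,0.027,-6.53,-10.43,-2.62,0.001,0.124,5.365,0.27,0.15,1.054
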
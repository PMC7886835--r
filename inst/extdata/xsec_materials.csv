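material,energy_keV,mu_rho,mutr_rho,f_pe,f_co,f_ra
air,5,40.2700,39.50000,0.985385660564,0.0048714464785,0.009742892957
air,6,23.4100,22.70000,0.974955258421,0.0083482471931,0.016696494386
air,8,9.9210,9.44600,0.941344766427,0.0195517445242,0.039103489048
air,10,5.1200,4.74200,0.890482718347,0.0376057737375,0.071911507916
air,15,1.6140,1.33400,0.783283561025,0.1171511566469,0.099565282328
air,20,0.7779,0.53890,0.647000872738,0.2388257183228,0.114173408939
air,30,0.3538,0.15370,0.384436552099,0.5076929895757,0.107870458325
air,40,0.2485,0.06833,0.216189073685,0.7001341146753,0.083676811640
air,50,0.2080,0.04098,0.126370642323,0.8115537277736,0.062075629903
air,60,0.1875,0.03041,0.078720579200,0.8748112349109,0.046468185890
air,80,0.1662,0.02407,0.036368845172,0.9356742823380,0.027956872490
air,100,0.1541,0.02325,0.020341937872,0.9612760939954,0.018381968132
air,150,0.1356,0.02496,0.008168062226,0.9834735210421,0.008358416732
lung,5,42.6700,42.00000,0.984663197409,0.0051122675302,0.010224535060
lung,6,24.0500,23.50000,0.972891871323,0.0090360428924,0.018072085785
lung,8,10.3700,10.05000,0.937600643292,0.0207997855694,0.041599571139
lung,10,5.3290,4.94400,0.887356176579,0.0401768071205,0.072467016300
lung,15,1.6730,1.37400,0.773577177854,0.1256755576242,0.100747264522
lung,20,0.8096,0.55030,0.629766099278,0.2551708235644,0.115063077157
lung,30,0.3756,0.15570,0.361648066473,0.5317776275804,0.106574305946
lung,40,0.2683,0.06947,0.197631331015,0.7210802665815,0.081288402404
lung,50,0.2269,0.04223,0.113053242084,0.8272614115747,0.059685346342
lung,60,0.2059,0.03190,0.069775515214,0.8858413076616,0.044383177124
lung,80,0.1837,0.02597,0.032137720863,0.9413328324090,0.026529446728
lung,100,0.1707,0.02546,0.017624587111,0.9649702188013,0.017405194088
lung,150,0.1505,0.02764,0.006769301656,0.9853318285673,0.007898869776
soft_tissue,5,42.6700,42.00000,0.984663197409,0.0051122675302,0.010224535060
soft_tissue,6,24.0500,23.50000,0.972891871323,0.0090360428924,0.018072085785
soft_tissue,8,10.3700,10.05000,0.937600643292,0.0207997855694,0.041599571139
soft_tissue,10,5.3290,4.94400,0.887356176579,0.0401768071205,0.072467016300
soft_tissue,15,1.6730,1.37400,0.773577177854,0.1256755576242,0.100747264522
soft_tissue,20,0.8096,0.55030,0.629766099278,0.2551708235644,0.115063077157
soft_tissue,30,0.3756,0.15570,0.361648066473,0.5317776275804,0.106574305946
soft_tissue,40,0.2683,0.06947,0.197631331015,0.7210802665815,0.081288402404
soft_tissue,50,0.2269,0.04223,0.113053242084,0.8272614115747,0.059685346342
soft_tissue,60,0.2059,0.03190,0.069775515214,0.8858413076616,0.044383177124
soft_tissue,80,0.1837,0.02597,0.032137720863,0.9413328324090,0.026529446728
soft_tissue,100,0.1707,0.02546,0.017624587111,0.9649702188013,0.017405194088
soft_tissue,150,0.1505,0.02764,0.006769301656,0.9853318285673,0.007898869776
bone,5,212.0000,203.00000,0.997137213765,0.0009542620784,0.001908524157
bone,6,128.0000,122.00000,0.995276412546,0.0015745291514,0.003149058303
bone,8,53.0000,50.20000,0.988677291931,0.0037742360230,0.007548472046
bone,10,28.5100,26.80000,0.979106437881,0.0069645207062,0.013929041412
bone,15,9.0320,8.38800,0.935233355306,0.0215888815646,0.043177763129
bone,20,4.0010,3.60100,0.877426092439,0.0478850862858,0.074688821275
bone,30,1.3310,1.07000,0.764354582438,0.1391697673388,0.096475650223
bone,40,0.6655,0.45070,0.625269622067,0.2696022636831,0.105128114250
bone,50,0.4242,0.23360,0.487219984630,0.4103683984145,0.102411616956
bone,60,0.3148,0.14000,0.369542176083,0.5373346684414,0.093123155475
bone,80,0.2229,0.06896,0.210398470221,0.7194648902130,0.070136639566
bone,100,0.1855,0.04585,0.125107240829,0.8235136995948,0.051379059576
bone,150,0.1480,0.03183,0.045000419604,0.9292329628292,0.025766617567
water,5,42.6700,42.00000,0.984663197409,0.0051122675302,0.010224535060
water,6,24.0500,23.50000,0.972891871323,0.0090360428924,0.018072085785
water,8,10.3700,10.05000,0.937600643292,0.0207997855694,0.041599571139
water,10,5.3290,4.94400,0.887356176579,0.0401768071205,0.072467016300
water,15,1.6730,1.37400,0.773577177854,0.1256755576242,0.100747264522
water,20,0.8096,0.55030,0.629766099278,0.2551708235644,0.115063077157
water,30,0.3756,0.15570,0.361648066473,0.5317776275804,0.106574305946
water,40,0.2683,0.06947,0.197631331015,0.7210802665815,0.081288402404
water,50,0.2269,0.04223,0.113053242084,0.8272614115747,0.059685346342
water,60,0.2059,0.03190,0.069775515214,0.8858413076616,0.044383177124
water,80,0.1837,0.02597,0.032137720863,0.9413328324090,0.026529446728
water,100,0.1707,0.02546,0.017624587111,0.9649702188013,0.017405194088
water,150,0.1505,0.02764,0.006769301656,0.9853318285673,0.007898869776
copper,5,189.9000,180.00000,0.997166606364,0.0009444645453,0.001888929091
copper,6,115.6000,108.00000,0.995363063020,0.0015456456601,0.003091291320
copper,8,52.5500,48.80000,0.989875803707,0.0033747320977,0.006749464195
copper,10,215.9000,148.40000,0.997553956585,0.0008153478051,0.001630695610
copper,15,74.0500,57.88000,0.992996464053,0.0023345119824,0.004669023965
copper,20,33.7900,27.88000,0.984919734553,0.0050267551489,0.010053510298
copper,30,10.9200,9.34900,0.954884199191,0.0150386002697,0.030077200539
copper,40,4.8620,4.16300,0.910946320544,0.0327162664993,0.056337412957
copper,50,2.6130,2.19200,0.875845773161,0.0590625592161,0.065091667623
copper,60,1.5930,1.29000,0.833812775092,0.0941392875525,0.072047937355
copper,80,0.7630,0.55810,0.733442994923,0.1863383447505,0.080218660327
copper,100,0.4584,0.31480,0.623153481942,0.2954453988207,0.081401119238
copper,150,0.2217,0.10600,0.382700361395,0.5499557245087,0.067343914096
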
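hybrid,concentration,part,raffinose,sorbitol,trehalose,glucose,fructose,sucrose
ZP434,control,radicle,7.9931,3.0579,62.3965,68.5418,254.3825,841.9138
ZP434,control,plumule,12.7217,3.3389,43.8622,222.6542,271.2674,649.1978
ZP434,control,ros,50.5664,5.5136,73.8872,1046.259,261.2864,130.0573
ZP434,5.20e-09,radicle,14.2604,0.8227,32.2406,72.4003,110.0534,1210.0050
ZP434,5.20e-12,radicle,7.0938,3.5868,22.2901,49.8711,114.6543,1338.2100
ZP434,5.20e-15,radicle,5.0012,4.5679,29.6699,38.5214,178.4462,2169.5330
ZP434,5.20e-09,plumule,17.0156,5.1357,115.7239,184.6312,252.1725,88.6012
ZP434,5.20e-12,plumule,11.3800,1.4866,20.5768,41.0811,112.2853,2603.9130
ZP434,5.20e-15,plumule,7.4408,1.1033,34.9129,212.4535,101.4513,2298.5210
ZP434,5.20e-09,ros,34.1855,3.5327,84.7864,430.8231,117.0468,45.8835
ZP434,5.20e-12,ros,32.8532,3.5152,226.9110,560.7511,116.8894,87.8414
ZP434,5.20e-15,ros,21.9895,0.8227,333.7512,624.8609,162.6723,178.8451
ZP704,control,radicle,6.8337,2.7508,84.8762,51.9034,61.4431,2527.6880
ZP704,control,plumule,28.7644,0.0059,53.2387,76.5831,110.2051,187.2433
ZP704,control,ros,27.8861,0.4146,92.7478,1042.7689,214.9874,46.5897
ZP704,5.20e-09,radicle,45.3488,1.1700,73.8400,74.7900,69.5500,2206.3300
ZP704,5.20e-12,radicle,34.9993,4.8500,217.1900,580.6900,585.6300,652.5600
ZP704,5.20e-15,radicle,8.0947,0.6600,422.0900,101.2300,32.6200,2171.8300
ZP704,5.20e-09,plumule,32.9978,3.1400,406.4000,1070.4500,602.9000,4642.3400
ZP704,5.20e-12,plumule,76.9934,3.4400,264.4900,1054.3900,592.3500,4841.0200
ZP704,5.20e-15,plumule,9.9465,5.5300,1002.3500,11.5700,26.5400,1148.2400
ZP704,5.20e-09,ros,32.4110,1.6000,90.4700,845.1300,300.3500,137.6500
ZP704,5.20e-12,ros,9.8344,0.2700,176.2900,773.3400,255.6000,49.6000
ZP704,5.20e-15,ros,2.7681,0.2100,208.4300,175.2100,34.4500,4.7700
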
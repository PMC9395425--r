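sex,age_years,L,M,S
F,5,1,111.19507824029188,0.042
F,5.25,1,112.67650484728128,0.042
F,5.5,1,114.12020686812158,0.042
F,5.75,1,115.52792706658863,0.042
F,6,1,116.90157016331665,0.042
F,6.25,1,118.24325840579475,0.042
F,6.5,1,119.55540218083517,0.042
F,6.75,1,120.84078937003277,0.042
F,7,1,122.10269772879157,0.042
F,7.25,1,123.34503497415267,0.042
F,7.5,1,124.57251121925592,0.042
F,7.75,1,125.79084740206531,0.042
F,8,1,127.00702059458838,0.042
F,8.25,1,128.2295412162133,0.042
F,8.5,1,129.46874620101667,0.042
F,8.75,1,130.7370732967958,0.042
F,9,1,132.04925156656304,0.042
F,9.25,1,133.42229900038538,0.042
F,9.5,1,134.87516041170858,0.042
F,9.75,1,136.42775692946145,0.042
F,10,1,138.09917977485588,0.042
F,10.25,1,139.90480036410796,0.042
F,10.5,1,141.85226729107507,0.042
F,10.75,1,143.9367929917209,0.042
F,11,1,146.13677994625192,0.042
F,11.25,1,148.41146542544453,0.042
F,11.5,1,150.7023944052366,0.042
F,11.75,1,152.93967184827062,0.042
F,12,1,155.052115060919,0.042
F,12.25,1,156.97849732219677,0.042
F,12.5,1,158.67633649640095,0.042
F,12.75,1,160.12575099592917,0.042
F,13,1,161.32808423349306,0.042
F,13.25,1,162.3008951481752,0.042
F,13.5,1,163.0716136346581,0.042
F,13.75,1,163.67173669701984,0.042
F,14,1,164.13253670414386,0.042
F,14.25,1,164.48245015164147,0.042
F,14.5,1,164.74585553267806,0.042
F,14.75,1,164.94280256584344,0.042
F,15,1,165.08929283326287,0.042
F,15.25,1,165.1978184414614,0.042
F,15.5,1,165.27797362629622,0.042
F,15.75,1,165.33703785578888,0.042
F,16,1,165.38048431819286,0.042
F,16.25,1,165.4124002075912,0.042
F,16.5,1,165.43582217114806,0.042
F,16.75,1,165.45299771479048,0.042
F,17,1,165.4655855051837,0.042
F,17.25,1,165.47480700386888,0.042
F,17.5,1,165.48156025151533,0.042
F,17.75,1,165.48650469949354,0.042
F,18,1,165.49012415418036,0.042
M,5,1,107.20016690867182,0.042
M,5.25,1,109.01013383669932,0.042
M,5.5,1,110.77364541041297,0.042
M,5.75,1,112.49202817330318,0.042
M,6,1,114.16660877909084,0.042
M,6.25,1,115.79872363726926,0.042
M,6.5,1,117.38973099500173,0.042
M,6.75,1,118.9410261307703,0.042
M,7,1,120.4540605142719,0.042
M,7.25,1,121.93036600940013,0.042
M,7.5,1,123.37158547010708,0.042
M,7.75,1,124.77951140877306,0.042
M,8,1,126.15613480616625,0.042
M,8.25,1,127.50370657598158,0.042
M,8.5,1,128.82481467450492,0.042
M,8.75,1,130.12248030756388,0.042
M,9,1,131.40027703252358,0.042
M,9.25,1,132.6624765973468,0.042
M,9.5,1,133.9142247776341,0.042
M,9.75,1,135.1617487251925,0.042
M,10,1,136.4125935651626,0.042
M,10.25,1,137.6758788665217,0.042
M,10.5,1,138.96255331850475,0.042
M,10.75,1,140.28560614078688,0.042
M,11,1,141.66016406421406,0.042
M,11.25,1,143.10336203136148,0.042
M,11.5,1,144.6338270815927,0.042
M,11.75,1,146.27057032343762,0.042
M,12,1,148.0310694520988,0.042
M,12.25,1,149.9283926501573,0.042
M,12.5,1,151.96742648587232,0.042
M,12.75,1,154.14066782503252,0.042
M,13,1,156.42457395583259,0.042
M,13.25,1,158.77791761780855,0.042
M,13.5,1,161.14358505307214,0.042
M,13.75,1,163.4544554048069,0.042
M,14,1,165.64249774845493,0.042
M,14.25,1,167.64871979716858,0.042
M,14.5,1,169.43105236213617,0.042
M,14.75,1,170.9680894641256,0.042
M,15,1,172.2583168417845,0.042
M,15.25,1,173.31602177697695,0.042
M,15.5,1,174.16575627360606,0.042
M,15.75,1,174.83699993690612,0.042
M,16,1,175.3599836385649,0.042
M,16.25,1,175.76295459933175,0.042
M,16.5,1,176.07072372527816,0.042
M,16.75,1,176.3041544581424,0.042
M,17,1,176.4802440334143,0.042
M,17.25,1,176.61251952095003,0.042
M,17.5,1,176.7115596986946,0.042
M,17.75,1,176.78552964693844,0.042
M,18,1,176.84066930003806,0.042
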
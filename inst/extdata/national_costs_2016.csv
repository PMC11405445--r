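row_type,infection,group,burden_central,burden_low,burden_high,los,att_cost_year,att_cost_2017,total_central,total_low,total_high
infection,vap,device,62700,18200,220700,12.47,39124,40009,2508545823,728158437,8829921263
infection,ssi,device,110800,30200,411200,8.42,23174,23698,2625749064,715682506,9744657174
infection,cdi,device,106100,29900,381400,5.52,12339,12618,1338764859,377276808,4812487440
infection,cauti,device,38600,9600,155300,5.26,12060,12333,476044398,118394462,1915277074
infection,bsi,device,83600,21800,321300,7.36,20607,21073,1761680926,459385696,6770670830
subtotal,device_subtotal,device,401800,109700,1489900,NA,NA,NA,8710785070,2398897909,32073013781
infection,pneumonia,nondevice,114000,33000,400900,4.73,11599,11861,1352166271,391416552,4755118054
infection,gi,nondevice,40200,11400,144600,4.63,15643,15996,643042318,182355284,2313032815
infection,uti,nondevice,24100,6000,97200,3.89,8688,8884,214105420,53304254,863528915
infection,eentm,nondevice,33600,7300,151100,2.99,8208,8394,282029528,61274272,1268293503
infection,lrti,nondevice,29100,6000,133900,4.24,12013,12285,357486033,73708460,1644927143
infection,ssti,nondevice,35500,7800,156800,4.61,11113,11364,403438960,88642927,1781950113
infection,cvs,nondevice,1900,0,23000,7.92,22413,22920,43547605,0,527155221
infection,bji,nondevice,3200,200,32500,6.77,16934,17317,55414465,3463404,562803163
infection,cns,nondevice,1900,0,23000,7.58,25861,26445,50246030,0,608241411
infection,rti,nondevice,1900,0,23000,3.61,9647,9865,18743644,0,226896744
infection,systemic,nondevice,0,0,15300,6.01,15456,15805,0,0,241817008
subtotal,nondevice_subtotal,nondevice,285400,71700,1201300,NA,NA,NA,3420220276,854165154,14793764090
grand,all_infections,all,687200,181400,2691200,NA,NA,NA,12131005346,3253063063,46866777870
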
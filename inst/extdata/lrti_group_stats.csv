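year,group,n,cost_mean,cost_median,cost_mode,cost_min,cost_max,los_mean,los_median,los_mode,los_min,los_max,ndx_mean,ndx_sd,npr_mean,npr_sd,age_mean,age_min,age_max,severity_mean,severity_sd,risk_mean,risk_sd,wage_mean,wage_sd
2011,secondary,31266,26839,11335,3186,101,1620419,10.35,6,3,3,365,13.10,6.45,2.30,3.50,54,0,111,2.86,0.92,2.34,1.09,0.9900,0.156
2011,principal,40735,7415,3833,360,78,766034,3.83,3,2,1,234,6.26,5.26,0.55,1.49,27,0,108,1.89,0.87,1.40,0.74,0.9871,0.155
2011,none,156330,13671,7784,78,31,1089791,5.63,4,2,1,364,11.05,6.10,1.43,2.26,59,0,109,2.49,0.95,2.12,1.03,0.9969,0.159
2016,secondary,167961,29367,14237,9445,23,2850000,10.37,7,3,3,365,17.59,6.37,2.83,3.63,64,0,90,3.14,0.78,2.84,0.96,0.9950,0.191
2016,principal,43213,9179,5325,1465,63,1142474,4.24,3,2,1,188,8.94,6.69,0.90,1.75,35,0,90,2.13,0.90,1.69,0.90,1.0014,0.194
2016,none,839601,14398,8504,3148,19,1636440,5.41,4,2,1,354,13.58,6.53,1.53,2.35,62,0,90,2.53,0.90,2.29,1.01,0.9960,0.194
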
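year,parameter,estimate,std_error,ci_lower,ci_upper,n_fit
2011,intercept,-4180.48,91.1787,-4359.192,-4001.767,40643
2011,los,1324.03,12.2049,1300.1083,1347.9519,40643
2011,n_diagnoses,89.38,5.97,77.6787,101.0814,40643
2011,n_procedures,1916.808,41.1644,1836.1245,1997.4906,40643
2011,urban_teaching,272.0654,22.1886,228.5752,315.5556,40643
2011,small_bedsize,-551.727,33.933,-618.236,-485.217,40643
2011,age,2.3119,0.574,1.1868,3.437,40643
2011,severity_index,150.6755,27.3487,97.0713,204.2796,40643
2011,mortality_risk_index,103.7112,39.6886,25.9206,181.5019,40643
2011,wage_index,4016.947,78.7623,3862.5711,4171.3228,40643
2016,intercept,-4428.32,92.3444,-4609.313,-4247.32,43111
2016,los,1476.475,10.8909,1455.129,1497.8214,43111
2016,n_diagnoses,66.0973,4.87,56.552,75.6426,43111
2016,n_procedures,1322.245,25.6503,1271.97,1372.5205,43111
2016,urban_teaching,334.9984,28.5321,279.075,390.9218,43111
2016,small_bedsize,-649.742,37.0221,-722.3062,-577.1779,43111
2016,age,-2.2123,0.6268,-3.4408,-0.9838,43111
2016,severity_index,447.6694,26.6918,395.3529,499.9858,43111
2016,mortality_risk_index,-145.316,29.054,-202.2622,-88.3695,43111
2016,wage_index,4347.947,71.203,4208.385,4487.5038,43111
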
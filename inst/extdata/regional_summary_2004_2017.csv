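year,density,mean_distance,transformed_mean_distance,n_practices,n_ip_practices,n_patients
2004,0.136,2.089,35.03,197,28,25979
2005,0.151,2.020,36.60,192,29,26491
2006,0.137,2.007,29.00,217,37,27360
2007,0.139,1.995,25.73,209,33,27621
2008,0.144,1.922,16.81,225,37,27209
2009,0.151,1.933,24.77,221,35,27408
2010,0.161,1.893,17.30,218,35,27306
2011,0.157,1.879,10.61,222,35,27804
2012,0.144,1.923,18.19,229,34,28032
2013,0.150,1.888,10.97,228,34,28612
2014,0.153,1.877,8.82,230,36,28151
2015,0.162,1.881,14.25,220,35,28487
2016,0.152,1.890,13.86,234,36,28999
2017,0.160,1.884,14.73,225,36,29421
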
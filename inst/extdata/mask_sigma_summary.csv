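flight_date,mask,max_sigma_c,mean_sigma_c
2017-11-16,grvi,6.0,2.3
2017-12-06,grvi,7.1,2.2
2017-12-20,grvi,7.8,2.0
2018-01-07,grvi,9.2,2.1
2018-01-14,grvi,4.9,1.8
2017-11-16,grvi_ta9,2.6,1.3
2017-12-06,grvi_ta9,3.2,1.8
2017-12-20,grvi_ta9,3.3,1.6
2018-01-07,grvi_ta9,2.7,1.5
2018-01-14,grvi_ta9,2.5,1.2
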
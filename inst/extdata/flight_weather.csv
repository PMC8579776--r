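flight_date,start_time,ta_c,rh_pct,ws_ms,vpd_kpa
2017-11-16,13:33,32.83,38.78,4.02,3.05
2017-12-06,11:00,32.48,22.89,2.85,3.77
2017-12-20,11:56,32.14,14.39,2.29,4.11
2018-01-07,12:42,29.79,15.85,1.44,3.53
2018-01-14,12:47,30.11,27.76,2.43,3.09
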
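year,model,nugget,sill,range_m,dsd_pct
2010,gaussian,0.1585,1.6217,59902,9.77
2011,gaussian,0.1316,1.7403,54541,7.52
2012,gaussian,0.1267,1.7982,57355,7.00
2013,gaussian,0.1287,1.7805,63124,7.22
2014,gaussian,0.1294,1.7170,55485,7.51
2015,gaussian,0.1287,1.8061,62548,7.12
2016,gaussian,0.1308,1.7594,61548,7.39
2017,gaussian,0.1296,1.7412,58563,7.44
2018,gaussian,0.1356,1.7220,62551,7.87
2019,gaussian,0.1318,1.7792,58961,7.36
2020,gaussian,0.1422,1.7163,60512,8.27
2021,gaussian,0.1356,1.7313,56548,7.83
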
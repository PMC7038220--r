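feature,mean_normal,sd_normal,mean_asd,sd_asd,p,t
LSDA13,-1756.04,1126.778,-801.964,1080.377,0.000309,3.786288
LSDA8,-1402.45,544.1245,-2004.56,909.222,0.000711,3.55602
LSDA9,-886.62,264.4797,-314.428,1157.47,0.003981,3.041854
LSDA11,1918.153,1133.604,2545.265,1297.72,0.026577,2.262406
LSDA7,-583.943,600.9221,-805.991,116.416,0.033149,2.209627
LSDA2,133.0712,364.5094,291.3328,311.3471,0.044995,2.040697
LSDA6,-833.493,651.3617,-998.316,145.0319,0.140299,1.505079
LSDA1,-385.252,98.16647,-548.472,803.8656,0.209993,1.273933
LSDA4,-531.886,140.8786,-567.485,125.164,0.246415,1.168582
LSDA5,-680.707,70.31738,-691.059,23.01104,0.397739,0.854162
LSDA14,-657.845,501.4798,-545.09,1308.884,0.614934,0.50615
LSDA21,-592.889,3.035538,-590.386,44.26157,0.723211,0.356711
LSDA10,796.1476,2058.705,922.609,867.6855,0.730657,0.346282
LSDA12,-5132.27,4467.789,-4754.77,5277.353,0.735127,0.339583
LSDA24,-1464.89,71.78779,-1461.35,7.848605,0.767,0.298501
LSDA23,-801.367,2047.65,-706.917,504.8907,0.786254,0.273003
LSDA28,1383.901,772.3631,1413.86,61.62772,0.815334,0.235248
LSDA27,1029.853,696.2088,1005.313,73.09999,0.832258,0.213319
LSDA29,585.8519,1.168018,585.4515,12.84125,0.845341,0.196346
LSDA22,-295.577,1400.244,-339.624,97.81121,0.849659,0.19091
LSDA17,445.7471,353.7109,485.0725,1609.695,0.880972,0.150629
LSDA15,460.2031,37.12207,463.1301,119.2549,0.883222,0.147686
LSDA19,-592.541,1998.428,-546.308,461.9218,0.891436,0.137369
LSDA20,-1035.72,1877.321,-993.439,381.1509,0.893739,0.134455
LSDA25,-588.542,1679.106,-621.33,116.2695,0.906315,0.118513
LSDA16,-1775.64,457.8857,-1799.15,1321.607,0.91614,0.105843
LSDA18,-1565.5,2122.529,-1523.15,1425.022,0.919109,0.101969
LSDA26,-663.813,14.99397,-664.267,26.89385,0.926769,0.092285
LSDA30,-653.938,158.0741,-653.208,37.69053,0.978273,0.027406
LSDA3,346.7321,107.2744,338.2296,2320.293,0.981649,0.023149
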
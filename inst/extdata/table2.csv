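plant,L0,L,W0,W,S0,S,H0,H
1,64.00,69.17,13.97,14.29,1113.60,1308.14,74.20,66.15
2,69.20,66.06,13.88,14.07,1141.80,1155.54,44.80,50.55
3,45.20,45.14,16.12,16.36,863.32,935.93,42.40,40.52
4,70.70,71.63,14.97,15.38,855.47,1230.96,64.40,59.10
5,70.10,77.67,13.11,13.88,1184.69,1371.95,60.00,60.86
6,104.40,108.94,16.78,16.54,1545.12,1551.94,135.70,128.24
7,104.90,102.05,10.75,11.09,1521.05,1441.25,126.30,119.19
8,71.20,64.87,12.54,12.11,1132.08,1147.46,108.20,107.02
9,132.40,131.95,12.66,13.48,1986.00,1881.59,134.50,130.37
10,110.70,115.75,13.99,14.16,1726.92,1994.75,130.40,124.37
11,180.10,170.69,12.59,13.48,2773.54,2084.64,174.50,182.54
12,180.70,172.21,13.79,14.80,3035.76,2887.03,156.70,147.38
13,143.30,141.21,10.13,10.56,2292.80,2278.85,142.70,143.12
14,197.30,186.36,9.59,10.20,3255.45,2890.01,201.90,194.59
15,181.20,177.19,9.88,10.52,2989.80,3033.35,191.20,187.77
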
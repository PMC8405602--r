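tag,transmitter,tagging_location,year_fledged,capture_group,start_date,end_date,gps_fixes,tracking_days,core50_km2,homerange95_km2
5 - Petitsata,OT-30,Kresna Gorge,2012,wild_caught,2020-03-19,2021-03-26,20492,373,8.532,359.259
1H - Wild 1H,OT-P33,Kresna Gorge,2016,wild_caught,2017-07-12,2018-05-13,19996,306,162.79,4176.175
1X - Terziev,OT-P33,Dadia,2017,wild_rehabilitated,2018-01-22,2021-03-26,74306,1160,33.33,2059.875
2H - Wild 2H,OT-P33,Kresna Gorge,2016,wild_caught,2017-07-12,2020-06-20,70453,1075,75.564,2890.259
56 - Survivor,OT-P33,Kresna Gorge,2014,reintroduced,2017-07-12,2018-09-20,32150,436,33.174,5320.03
A4 - Vrachan,OT-P33,Vrachanski Balkan,2011,reintroduced,2017-11-07,2019-09-16,32954,678,4.186,320.095
Alexis,OT-P33,Messolonghi,2017,wild_rehabilitated,2017-08-05,2019-05-27,7555,93,91.675,3163.986
B65 - Parvolet,OT-P33,Sinite Kamani,2016,reintroduced,2019-07-21,2021-03-27,37756,616,10.426,493.88
B69 - Balkan,OT-P33,Kresna Gorge,2016,wild_caught,2017-08-18,2018-02-06,8794,173,24.20,1978.353
B70-UG - Barcelona,OT-P33,Kresna Gorge,2015,reintroduced,2017-07-18,2017-09-07,4602,52,2.481,395.826
B71-XU - Barca,OT-P33,Kresna Gorge,2015,reintroduced,2017-08-03,2017-10-14,5429,73,1.437,184.891
BY1 - Gorlits,OT-30,Kresna Gorge,2018,wild_caught,2020-02-22,2021-03-26,24162,399,11.246,2380.805
BY3 - Svetislav 2,OT-50,Kresna Gorge,2018,wild_caught,2020-02-22,2021-01-23,16874,337,12.737,1434.072
BY7 - Michev,OT-30,Kresna Gorge,adult,wild_caught,2020-06-03,2020-07-14,3664,50,34.049,909.422
C1-M - Kresna,OT-P33,Vrachanski Balkan,2016,reintroduced,2018-02-08,2019-09-16,41357,586,4.392,275.712
C5 - Sunchitsa,OT-50,Kavadarci,2019,wild_caught,2019-10-30,2021-03-27,22230,329,13.736,1951.845
C7 - Svetislav,OT-50/OT-P33,Kavadarci/Kresna Gorge,2019,wild_caught,2020-09-04,2020-11-26,5547,84,31.373,921.962
C9 - Rakitna,OT-P33,Kresna Gorge,2018,wild_caught,2020-06-24,2021-03-27,19015,277,61.214,1823.193
Defile,OT-30,Kresna Gorge,2016,wild_caught,2020-07-29,2021-03-26,11187,241,5.372,370.085
E1 - Poison detective,OT-P33,Vrachanski Balkan,2014,wild_caught,2020-12-16,2021-03-27,3177,101,2.413,83.473
EX - Extreme,OT-50,Kresna Gorge,2019,wild_caught,2021-02-01,2021-03-27,2515,55,2.114,23.197
F4 - Stresher,OT-30,Vrachanski Balkan,2018,reintroduced,2019-12-06,2021-03-26,22863,477,2.852,143.784
F6 - Zelen,OT-30,Vrachanski Balkan,2018,reintroduced,2019-12-06,2021-03-26,27130,477,4.298,191.242
GD-22 - Giannis,OT-50,Messolonghi,,wild_rehabilitated,2020-03-05,2021-03-27,28774,388,72.197,1579.987
GS - Athanasios,OT-30,Messolonghi,2020,wild_rehabilitated,2021-01-24,2021-03-27,2929,63,9.368,137.276
H1 - Juanjo,OT-P33,Kotel,2016,wild_caught,2017-03-08,2019-10-28,68012,965,1.203,216.167
HW - Struma,OT-P33,Kresna Gorge,2015,reintroduced,2020-06-24,2021-03-27,18020,277,6.439,320.247
K2M - Mulhouse,OT-P33,Kresna Gorge,2016,reintroduced,2017-08-03,2018-02-01,11809,183,3.639,570.129
K3A-B2,OT-30,Messolonghi,2018,wild_rehabilitated,2020-03-06,2020-10-30,14463,239,24.37,470.309
K5M - Baumgart,OT-P33,Kotel,2011,reintroduced,2017-01-24,2018-01-27,21918,369,3.640,141.962
K7A-B5 - Dinos,OT-30,Messolonghi,adult,wild_rehabilitated,2020-03-06,2021-03-26,25435,386,106.767,3059.814
K9U - Kotel,OT-P33,Kresna Gorge,2014,reintroduced,2017-08-03,2018-05-13,19775,284,156.375,5308.372
M2 - Lars,OT-P33,Sinite Kamani,2017,reintroduced,2019-03-21,2020-08-19,40793,518,6.903,248.354
OX - De Doue,OT-P33,Kresna Gorge,2016,reintroduced,2016-12-15,2018-02-18,24310,431,37.522,1642.845
P-B2F - Niki,OT-P33,Vrachanski Balkan,2017,wild_caught,2017-10-10,2018-02-19,6951,133,27.995,479.693
V3 - Poison Spy,OT-P33,Kresna Gorge,2017,reintroduced,2018-03-13,2021-03-26,76431,1097,31.91,4690.052
V5 - Boev,OT-P33,Kresna Gorge,2017,reintroduced,2019-02-12,2019-04-24,4736,72,1.765,69.608
V8 - Sainte Croix,OT-P33,Kresna Gorge,2017,reintroduced,2018-05-03,2019-12-17,36784,595,7.128,1290.039
XE - Hemus,OT-30,Vrachanski Balkan,2017,reintroduced,2020-07-01,2021-03-27,15157,270,2.853,186.603
XJ - Nikola,OT-P33,Kotel,2015,reintroduced,2019-03-15,2021-03-27,53929,733,2.851,114.437
Y1 - Gorlitz,OT-P33,Kresna Gorge,2017,wild_caught,2020-01-24,2021-03-26,28916,428,33.858,3042.697
Y2 - Whitley (WFN),OT-30,Kresna Gorge,2017,wild_caught,2020-02-22,2021-03-24,15968,371,13.978,1481.232
Y4 - Vrachan 2,OT-P33,Kresna Gorge,2018,wild_caught,2020-01-24,2020-10-06,19530,257,34.959,2568.986
Y5 - Alexis 2,OT-P33,Kresna Gorge,2018,wild_caught,2019-11-01,2021-03-26,24041,347,39.265,3889.373
Y6 - Juanjo 2,OT-P33,Kresna Gorge,2018,wild_caught,2019-11-01,2021-03-26,31414,512,41.639,966.519
Y8 - Paris 2,OT-P33,Kresna Gorge,2018,wild_caught,2020-02-22,2021-03-25,19709,393,50.644,2273.77
Y9 - Sinanitsa,OT-P33,Kresna Gorge,2019,wild_caught,2020-06-24,2021-03-27,9061,111,86.372,1907.081
Z7 - Izvor,OT-30,Vrachanski Balkan,2017,reintroduced,2020-09-01,2021-03-27,5310,202,4.571,191.373
C2 - Nelson,OT-P33,Kresna Gorge,2018,wild_caught,2018-09-19,2018-10-26,1016,15,,
W0818 - Bistritsa,OT-30,Kresna Gorge,2019,wild_caught,2020-09-04,2021-03-26,2373,33,,
A4 - Ezerets,OT-P33,Kresna Gorge,2019,wild_caught,2020-09-04,2021-03-27,3536,38,,
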
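season,n,core50_mean,core50_median,core50_sd,core50_min,core50_max,hr95_mean,hr95_median,hr95_sd,hr95_min,hr95_max
spring,44,34.8602,8.9035,57.947,1.04,244.085,984.604,508.227,1120.12,14.837,4855.93
summer,55,26.2727,12.21,37.9947,1.233,193.352,1033.56,696.312,1041.45,110.111,5292.27
autumn,50,11.5356,6.305,11.7446,0.867,48.415,421.864,225.127,477.72,16.452,2187.2
winter,56,7.76018,5.1155,9.12612,0.096,44.963,258.682,129.543,298.938,2.1,1256.35
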
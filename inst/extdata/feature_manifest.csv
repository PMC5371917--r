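ordinal,name,axis,group,feature,units,registry_version
1,x_time_max,x,time,max,m/s2,1.0
2,x_time_min,x,time,min,m/s2,1.0
3,x_time_peak_to_peak,x,time,peak_to_peak,m/s2,1.0
4,x_time_variance,x,time,variance,(m/s2)^2,1.0
5,x_time_hist_entropy,x,time,hist_entropy,bits,1.0
6,x_fft_dom_freq,x,fft,dom_freq,Hz,1.0
7,x_fft_dom_mag,x,fft,dom_mag,m/s2,1.0
8,x_fft_centroid,x,fft,centroid,Hz,1.0
9,x_fft_spectral_entropy,x,fft,spectral_entropy,bits,1.0
10,x_fft_band_0_3,x,fft,band_0_3,fraction,1.0
11,x_fft_band_3_12,x,fft,band_3_12,fraction,1.0
12,x_dct_c1,x,dct,c1,m/s2,1.0
13,x_dct_c2,x,dct,c2,m/s2,1.0
14,x_dct_c3,x,dct,c3,m/s2,1.0
15,x_dct_c4,x,dct,c4,m/s2,1.0
16,x_dct_energy_frac_10,x,dct,energy_frac_10,fraction,1.0
17,x_zt_r095_a22,x,zt,r095_a22,magnitude,1.0
18,x_zt_r095_a45,x,zt,r095_a45,magnitude,1.0
19,x_zt_r095_a90,x,zt,r095_a90,magnitude,1.0
20,x_zt_r095_a135,x,zt,r095_a135,magnitude,1.0
21,x_bispec_max,x,bispec,max,(m/s2)^3,1.0
22,x_bispec_mean,x,bispec,mean,(m/s2)^3,1.0
23,x_bispec_sum,x,bispec,sum,(m/s2)^3,1.0
24,x_bispec_entropy_p1,x,bispec,entropy_p1,bits,1.0
25,x_bispec_entropy_p2,x,bispec,entropy_p2,bits,1.0
26,x_bispec_peak_f1,x,bispec,peak_f1,Hz,1.0
27,x_wb_max,x,wb,max,(m/s2)^3,1.0
28,x_wb_mean,x,wb,mean,(m/s2)^3,1.0
29,x_wb_entropy,x,wb,entropy,bits,1.0
30,x_wb_diag_max,x,wb,diag_max,(m/s2)^3,1.0
31,x_wb_diag_peak_freq,x,wb,diag_peak_freq,Hz,1.0
32,x_wt_diag_max,x,wt,diag_max,(m/s2)^4,1.0
33,x_wt_diag_mean,x,wt,diag_mean,(m/s2)^4,1.0
34,x_wt_diag_entropy,x,wt,diag_entropy,bits,1.0
35,y_time_max,y,time,max,m/s2,1.0
36,y_time_min,y,time,min,m/s2,1.0
37,y_time_peak_to_peak,y,time,peak_to_peak,m/s2,1.0
38,y_time_variance,y,time,variance,(m/s2)^2,1.0
39,y_time_hist_entropy,y,time,hist_entropy,bits,1.0
40,y_fft_dom_freq,y,fft,dom_freq,Hz,1.0
41,y_fft_dom_mag,y,fft,dom_mag,m/s2,1.0
42,y_fft_centroid,y,fft,centroid,Hz,1.0
43,y_fft_spectral_entropy,y,fft,spectral_entropy,bits,1.0
44,y_fft_band_0_3,y,fft,band_0_3,fraction,1.0
45,y_fft_band_3_12,y,fft,band_3_12,fraction,1.0
46,y_dct_c1,y,dct,c1,m/s2,1.0
47,y_dct_c2,y,dct,c2,m/s2,1.0
48,y_dct_c3,y,dct,c3,m/s2,1.0
49,y_dct_c4,y,dct,c4,m/s2,1.0
50,y_dct_energy_frac_10,y,dct,energy_frac_10,fraction,1.0
51,y_zt_r095_a22,y,zt,r095_a22,magnitude,1.0
52,y_zt_r095_a45,y,zt,r095_a45,magnitude,1.0
53,y_zt_r095_a90,y,zt,r095_a90,magnitude,1.0
54,y_zt_r095_a135,y,zt,r095_a135,magnitude,1.0
55,y_bispec_max,y,bispec,max,(m/s2)^3,1.0
56,y_bispec_mean,y,bispec,mean,(m/s2)^3,1.0
57,y_bispec_sum,y,bispec,sum,(m/s2)^3,1.0
58,y_bispec_entropy_p1,y,bispec,entropy_p1,bits,1.0
59,y_bispec_entropy_p2,y,bispec,entropy_p2,bits,1.0
60,y_bispec_peak_f1,y,bispec,peak_f1,Hz,1.0
61,y_wb_max,y,wb,max,(m/s2)^3,1.0
62,y_wb_mean,y,wb,mean,(m/s2)^3,1.0
63,y_wb_entropy,y,wb,entropy,bits,1.0
64,y_wb_diag_max,y,wb,diag_max,(m/s2)^3,1.0
65,y_wb_diag_peak_freq,y,wb,diag_peak_freq,Hz,1.0
66,y_wt_diag_max,y,wt,diag_max,(m/s2)^4,1.0
67,y_wt_diag_mean,y,wt,diag_mean,(m/s2)^4,1.0
68,y_wt_diag_entropy,y,wt,diag_entropy,bits,1.0
69,z_time_max,z,time,max,m/s2,1.0
70,z_time_min,z,time,min,m/s2,1.0
71,z_time_peak_to_peak,z,time,peak_to_peak,m/s2,1.0
72,z_time_variance,z,time,variance,(m/s2)^2,1.0
73,z_time_hist_entropy,z,time,hist_entropy,bits,1.0
74,z_fft_dom_freq,z,fft,dom_freq,Hz,1.0
75,z_fft_dom_mag,z,fft,dom_mag,m/s2,1.0
76,z_fft_centroid,z,fft,centroid,Hz,1.0
77,z_fft_spectral_entropy,z,fft,spectral_entropy,bits,1.0
78,z_fft_band_0_3,z,fft,band_0_3,fraction,1.0
79,z_fft_band_3_12,z,fft,band_3_12,fraction,1.0
80,z_dct_c1,z,dct,c1,m/s2,1.0
81,z_dct_c2,z,dct,c2,m/s2,1.0
82,z_dct_c3,z,dct,c3,m/s2,1.0
83,z_dct_c4,z,dct,c4,m/s2,1.0
84,z_dct_energy_frac_10,z,dct,energy_frac_10,fraction,1.0
85,z_zt_r095_a22,z,zt,r095_a22,magnitude,1.0
86,z_zt_r095_a45,z,zt,r095_a45,magnitude,1.0
87,z_zt_r095_a90,z,zt,r095_a90,magnitude,1.0
88,z_zt_r095_a135,z,zt,r095_a135,magnitude,1.0
89,z_bispec_max,z,bispec,max,(m/s2)^3,1.0
90,z_bispec_mean,z,bispec,mean,(m/s2)^3,1.0
91,z_bispec_sum,z,bispec,sum,(m/s2)^3,1.0
92,z_bispec_entropy_p1,z,bispec,entropy_p1,bits,1.0
93,z_bispec_entropy_p2,z,bispec,entropy_p2,bits,1.0
94,z_bispec_peak_f1,z,bispec,peak_f1,Hz,1.0
95,z_wb_max,z,wb,max,(m/s2)^3,1.0
96,z_wb_mean,z,wb,mean,(m/s2)^3,1.0
97,z_wb_entropy,z,wb,entropy,bits,1.0
98,z_wb_diag_max,z,wb,diag_max,(m/s2)^3,1.0
99,z_wb_diag_peak_freq,z,wb,diag_peak_freq,Hz,1.0
100,z_wt_diag_max,z,wt,diag_max,(m/s2)^4,1.0
101,z_wt_diag_mean,z,wt,diag_mean,(m/s2)^4,1.0
102,z_wt_diag_entropy,z,wt,diag_entropy,bits,1.0
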
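year,class,b0.1_0.2,b0.2_0.3,b0.3_0.4,b0.4_0.5,b0.5_0.6,b0.6_0.7,b0.7_0.8,b0.8_0.9,b0.9_1.0
1980,SPARTINA_ALTERNIFLORA,0,0,0,0,0,0.66,1.41,1.84,1.56
1980,SUAEDA_SALSA,0,0,0,2.68,6.69,7.78,9.38,10.76,9.08
1980,PHRAGMITES_AUSTRALIS,0.06,6.88,10.23,8.94,8.39,6,2.76,1.31,0.94
1985,SPARTINA_ALTERNIFLORA,0,0,0,0,0,1.06,1.88,2.05,3.46
1985,SUAEDA_SALSA,0,0,0,0.38,4.04,8.92,9.23,8.15,7.45
1985,PHRAGMITES_AUSTRALIS,0.76,9.85,10.13,12.03,9.36,3.92,2.4,1.83,0.81
1990,SPARTINA_ALTERNIFLORA,0,0,0,0,0,0.22,1.07,1.6,3.58
1990,SUAEDA_SALSA,0,0,0,0.08,3.08,8.95,12.94,11.04,10.45
1990,PHRAGMITES_AUSTRALIS,0.04,6.05,9.74,10.45,11.61,6.9,2.73,1.29,0.73
1995,SPARTINA_ALTERNIFLORA,0,0,0,0,0,0.5,1.19,1.7,5.93
1995,SUAEDA_SALSA,0,0,0,1.16,7.28,8.9,10.07,9.62,11.39
1995,PHRAGMITES_AUSTRALIS,1.22,7.91,13.77,10.58,5.79,4.06,2.37,1.37,0.42
2000,SPARTINA_ALTERNIFLORA,0,0,0,0.47,1.69,2.12,3.61,6.37,7.79
2000,SUAEDA_SALSA,0,0,0,0.73,6.4,12.85,14.3,10.56,8.53
2000,PHRAGMITES_AUSTRALIS,0,3.09,8.14,10.17,8.03,2.41,0.64,0,0
2005,SPARTINA_ALTERNIFLORA,0,0,0.62,2.01,4.04,5.55,8.02,7.66,5.93
2005,SUAEDA_SALSA,0,1.3,3.69,12.21,9.88,4.72,1.77,1.19,0.15
2005,PHRAGMITES_AUSTRALIS,0,10.45,17.78,10.84,4.72,3.01,1.79,0.76,0.15
2010,SPARTINA_ALTERNIFLORA,0,0.01,1.65,4.85,6.06,7.04,9.19,8.12,5.66
2010,SUAEDA_SALSA,0,0.35,7.36,10.55,6.22,2.45,0.77,0.21,0
2010,PHRAGMITES_AUSTRALIS,0.02,18.85,22.06,8.09,4.02,2.63,0.91,0.08,0.11
2015,SPARTINA_ALTERNIFLORA,0,0,1.01,3.08,6.13,6.85,9.47,7.94,5.27
2015,SUAEDA_SALSA,0,1.47,5.76,4.19,1.77,1.98,0.42,0.25,0.01
2015,PHRAGMITES_AUSTRALIS,15.18,27.72,20.27,13.04,4.76,2.19,0.69,0.05,0
2017,SPARTINA_ALTERNIFLORA,0,0,0.63,3.19,5.75,6.94,9.17,8.07,5.22
2017,SUAEDA_SALSA,0,0.11,2.51,3.6,2.33,1.2,0.28,0,0
2017,PHRAGMITES_AUSTRALIS,9.6,26,22.23,16.92,7.61,3.91,1.08,0.21,0.01
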
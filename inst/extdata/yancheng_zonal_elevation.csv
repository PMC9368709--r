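year,class,min,max,mean
1980,SUAEDA_SALSA,0.33,2.72,1.42
1980,PHRAGMITES_AUSTRALIS,-0.97,4.36,1.71
1980,SPARTINA_ALTERNIFLORA,-0.07,1.59,0.73
1985,SUAEDA_SALSA,0.42,2.23,1.34
1985,PHRAGMITES_AUSTRALIS,-1.00,4.40,1.73
1985,SPARTINA_ALTERNIFLORA,0.19,1.84,0.91
1990,SUAEDA_SALSA,-0.84,2.96,1.52
1990,PHRAGMITES_AUSTRALIS,-0.96,4.43,1.78
1990,SPARTINA_ALTERNIFLORA,0.40,1.87,1.06
1995,SUAEDA_SALSA,0.57,3.04,1.60
1995,PHRAGMITES_AUSTRALIS,-0.61,4.47,1.82
1995,SPARTINA_ALTERNIFLORA,0.53,2.16,1.08
2000,SUAEDA_SALSA,0.71,2.57,1.57
2000,PHRAGMITES_AUSTRALIS,0.20,4.43,1.77
2000,SPARTINA_ALTERNIFLORA,-0.64,2.20,1.16
2005,SUAEDA_SALSA,0.95,2.61,1.54
2005,PHRAGMITES_AUSTRALIS,0.20,4.46,1.78
2005,SPARTINA_ALTERNIFLORA,0.91,2.32,1.40
2010,SUAEDA_SALSA,1.13,2.16,1.63
2010,PHRAGMITES_AUSTRALIS,-0.23,4.50,1.82
2010,SPARTINA_ALTERNIFLORA,-0.43,2.28,1.65
2015,SUAEDA_SALSA,1.19,2.11,1.66
2015,PHRAGMITES_AUSTRALIS,0.88,4.54,1.85
2015,SPARTINA_ALTERNIFLORA,0.30,2.53,1.88
2017,SUAEDA_SALSA,1.26,2.26,1.72
2017,PHRAGMITES_AUSTRALIS,0.51,4.47,1.85
2017,SPARTINA_ALTERNIFLORA,0.71,2.63,1.97
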
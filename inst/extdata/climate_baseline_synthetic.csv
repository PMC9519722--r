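year,t_annual,p_annual,t_winter
1986,7.73,977,-0.59
1987,7.7,1060,0.96
1988,7.68,1447,1.01
1989,7.03,993,-1.25
1990,8.34,1145,0.96
1991,7.58,1013,0.64
1992,7.66,1015,0.24
1993,7.47,1129,0.72
1994,7.71,1215,0.64
1995,7.84,1186,1.4
1996,7.63,1127,0.05
1997,7.03,1118,-0.93
1998,6.65,1079,-1.22
1999,6.95,1064,0.3
2000,6.46,1158,-0.71
2001,7.68,1258,1.83
2002,5.98,1168,-1.68
2003,8.43,1156,-0.5
2004,7.11,874,-1.35
2005,7.93,1163,1.94
2006,7.04,1079,0.1
2007,6.93,956,-0.34
2008,7.27,1211,0.15
2009,7.5,1232,0.29
2010,8.48,1129,0.54
2011,9.3,1302,2.21
2012,9.01,953,2.07
2013,7.46,1000,1.09
2014,8.43,1122,1.61
2015,7.29,1176,-0.81
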
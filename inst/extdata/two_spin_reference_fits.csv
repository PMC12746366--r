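subject,resonance,T1_corrected_ms,sigma_hz
1,TRP,1374.7,15.3
1,NAD_H2,1308.9,5.0
1,NAD_H6,1365.9,4.9
1,NAD_H4,1415.2,2.2
2,TRP,452.8,8.2
2,NAD_H2,647.6,6.3
2,NAD_H6,2562.9,2.7
2,NAD_H4,2761.3,1.2
3,TRP,662.0,9.2
3,NAD_H2,1038.0,7.4
3,NAD_H6,997.0,2.6
3,NAD_H4,1796.5,2.1
4,TRP,251.8,12.7
4,NAD_H2,926.6,6.1
4,NAD_H6,1539.0,3.7
4,NAD_H4,1520.0,2.9
5,TRP,759.5,12.1
5,NAD_H2,1025.3,6.0
5,NAD_H6,1329.0,2.9
5,NAD_H4,2192.2,4.8
6,TRP,146.2,16.9
6,NAD_H2,594.0,6.2
6,NAD_H6,NA,NA
6,NAD_H4,NA,NA
7,TRP,NA,NA
7,NAD_H2,816.6,6.7
7,NAD_H6,1100.4,3.6
7,NAD_H4,2658.6,4.9
8,TRP,709.2,12.0
8,NAD_H2,1042.3,2.0
8,NAD_H6,3706.1,2.9
8,NAD_H4,NA,NA
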
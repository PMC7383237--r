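variant,AA,CA,GA,TA,AC,CC,GC,TC,AG,CG,GG,TG,AT,CT,GT,TT
RTAG,ND,ND,519.7642,ND,464.1839,472.3599,44.0077,576.9966,ND,ND,521.7133,ND,ND,ND,445.3902,ND
QTAG,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND
RKAG,ND,ND,455.7295,ND,436.6402,588.4042,46.2730,512.2780,ND,ND,581.4086,ND,ND,ND,505.9775,ND
RTKG,ND,ND,501.7520,ND,605.5644,449.1014,49.8830,502.8665,ND,ND,571.4904,ND,ND,ND,445.4362,ND
RTAR,1808.9856,ND,ND,ND,1777.3808,ND,ND,ND,184.5897,1539.0809,1645.2480,1547.5656,2021.6848,ND,ND,ND
QKAG,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND
QTKG,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND
QTAR,1430.3146,ND,ND,ND,1237.4680,ND,ND,ND,113.9303,1326.0518,1152.1301,1147.2147,1278.8412,ND,ND,ND
RKKG,ND,ND,538.1571,ND,581.5375,567.7066,51.2420,520.0927,ND,ND,539.2411,ND,ND,ND,513.1431,ND
RKAR,658.7091,ND,ND,ND,618.5704,ND,ND,ND,64.4189,618.8634,693.3775,668.4391,804.0875,ND,ND,ND
RTKR,789.9731,ND,ND,ND,599.1173,ND,ND,ND,63.6263,585.2709,855.4423,786.2537,795.9049,ND,ND,ND
QKKG,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND,ND
QKAR,484.4156,ND,ND,ND,493.1129,ND,ND,ND,42.5656,569.6774,539.5671,493.7583,410.1585,ND,ND,ND
QTKR,413.0618,ND,ND,ND,515.5209,ND,ND,ND,57.9825,484.4144,511.5023,469.8701,661.7140,ND,ND,ND
RKKR,737.1967,ND,ND,ND,663.6771,ND,ND,ND,55.7724,573.5923,637.1222,647.1973,704.2041,ND,ND,ND
QKKR,497.7584,ND,ND,ND,471.3760,ND,ND,ND,47.7352,602.7709,498.2667,520.5101,527.8124,ND,ND,ND
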
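vowel	f1_hz	f2_hz
ih	429.4	2116.8
ih	400.6	2110.6
ih	422.5	2052
ih	418.5	2072.6
ih	408	2110.4
ih	374.7	2031.5
ih	406.8	2055.8
ih	401.6	2041.1
ih	422	2061.6
ih	411.5	2056.4
ih	412.7	2090.8
ih	406.9	2070.8
ih	416	2018.8
ih	415.9	2070.2
ih	374.2	2021.1
ih	444.2	2009.5
ih	431.1	2077.2
ih	423.9	2007.9
ih	405.5	2060.7
ih	432.4	2020.8
ih	414.1	2099.6
ih	417	2074.9
ih	394.9	2035.9
ih	446.4	2078
ih	420.9	2064.9
eh	568.9	1785.8
eh	586.3	1894.4
eh	573.2	1844.1
eh	598.1	1808
eh	578.4	1847.5
eh	585.8	1779.6
eh	567.7	1872.8
eh	572.7	1779.6
eh	592.4	1765.5
eh	572	1818.1
eh	587.5	1849.7
eh	593	1819.6
eh	586.4	1793.4
eh	584.8	1861.2
eh	558.8	1904.5
eh	585.1	1751.5
eh	557.6	1871.6
eh	610.7	1803.4
eh	571.9	1854.3
eh	592.7	1756.1
eh	599.4	1810.9
eh	590.1	1786.4
eh	614.2	1802.8
eh	574.8	1782.3
eh	598	1832.9
ae	766.9	1671.4
ae	736.1	1636
ae	740.9	1649.2
ae	725	1674.3
ae	762.9	1691.2
ae	755.1	1653.4
ae	716.8	1747.4
ae	771.7	1675.6
ae	724	1647.9
ae	726.1	1670.5
ae	718.5	1651.5
ae	723.5	1616.7
ae	738.7	1672.6
ae	754.6	1688.2
ae	732.2	1668.4
ae	741.4	1668
ae	739.9	1660.5
ae	766.1	1684.7
ae	786.2	1610.1
ae	725.8	1695.5
ae	779.3	1623.2
ae	783.4	1666.7
ae	749.2	1682.2
ae	761.1	1663.3
ae	713.7	1600.4
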
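food_code,context,group_id,fraction
10110000,core,1,1
10120000,discretionary,1,1
10210000,core,2,1
10220000,discretionary,2,1
10310000,core,3,1
10320000,discretionary,3,1
10410000,core,4,1
10420000,discretionary,4,1
10510000,core,5,1
10520000,discretionary,5,1
10610000,core,6,1
10620000,discretionary,6,1
10710000,core,7,1
10720000,discretionary,7,1
10810000,core,8,1
10820000,discretionary,8,1
10910000,core,9,1
10920000,discretionary,9,1
11010000,core,10,1
11020000,discretionary,10,1
11110000,core,11,1
11120000,discretionary,11,1
11210000,core,12,1
11220000,discretionary,12,1
11310000,core,13,1
11320000,discretionary,13,1
11410000,core,14,1
11420000,discretionary,14,1
11510000,core,15,1
11520000,discretionary,15,1
11610000,core,16,1
11620000,discretionary,16,1
11710000,core,17,1
11720000,discretionary,17,1
11810000,core,18,1
11820000,discretionary,18,1
11910000,core,19,1
11920000,discretionary,19,1
12010000,core,20,1
12020000,discretionary,20,1
12110000,core,21,1
12120000,discretionary,21,1
12210000,core,22,1
12220000,discretionary,22,1
12310000,core,23,1
12320000,discretionary,23,1
20000001,discretionary,8,0.5
20000001,discretionary,11,0.25
20000001,discretionary,17,0.15
20000001,discretionary,2,0.1
20000002,discretionary,8,0.45
20000002,discretionary,3,0.2
20000002,discretionary,15,0.25
20000002,discretionary,19,0.1
20000003,core,3,0.7
20000003,core,5,0.2
20000003,core,23,0.1
20000004,core,1,0.6
20000004,core,4,0.15
20000004,core,2,0.25
20000005,core,14,0.8
20000005,core,2,0.15
20000005,core,11,0.05
20000006,core,18,0.4
20000006,core,3,0.4
20000006,core,6,0.1
20000006,core,8,0.1
20000007,discretionary,11,0.5
20000007,discretionary,10,0.3
20000007,discretionary,15,0.2
20000008,discretionary,8,0.5
20000008,discretionary,19,0.3
20000008,discretionary,13,0.1
20000008,discretionary,23,0.1
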
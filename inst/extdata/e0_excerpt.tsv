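!!SBtab TableName='E0' TableType='QuantityMatrix' SBtabVersion='1.0'
!TimePoint	!Time	>Y0	SD_Y0	>Y1	SD_Y1	>Y2	SD_Y2	>Y3	SD_Y3
E0T0	0	84.47891	1	2672.089	1	3200.526	1	136,817.521	1
E0T1	0.01	84.47891	1	2672.089	1	3200.526	1	136,817.521	1
E0T2	0.02	84.47891	1	2672.089	1	3200.526	1	136,817.521	1
E0T3	0.03	84.47891	1	2672.089	1	3200.526	1	136,817.521	1
E0T2000	20	97.79736	1	2359.101	1	3192.558	1	137,475.511	1
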
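fraction	sequence	modifications	observed_mw	calculated_mw	observed_mz	theoretical_mz	charge	q_value
Fr41	TGGSLHAA		712.41	712.35	357.21	357.18	2	607.5
Fr41	VVPKAAPPPN		988.76	988.57	495.39	495.29	2	1343
Fr41	ATKPAN		600.41	600.32	301.21	301.17	2	1001.67
Fr41	SGAASASGAA		748.40	748.34	375.21	375.17	2	377
Fr41	HSAVFAAS		788.51	788.38	395.26	395.20	2	883.75
Fr41	NGNAASPGQPPLEVH		1486.84	1486.72	744.43	744.37	2	960
Fr41	HQWGGAPQH		1016.69	1016.46	509.35	509.24	2	794.44
Fr41	KFKGMNHINDIEKFK		1847.96	1847.97	616.99	617.00	3	1304
Fr41	GAVHAMVDTAKIHKGKK		1789.95	1790.00	597.66	597.67	3	1048.23
Fr42	AGGPNQPPN		850.48	850.39	426.25	426.20	2	941.11
Fr42	AANITVPAAN		940.58	940.50	471.30	471.26	2	1062
Fr42	DSLSAIGGAPDG		1058.45	1058.49	530.23	530.25	2	885.83
Fr42	SAGVLPWK		856.50	856.48	429.26	429.25	2	1500
Fr42	DGLIDGL		694.35	701.36	695.36	702.37	1	1270
Fr42	GDLIDVA		694.35	701.36	695.36	702.37	1	1270
Fr42	NQVTNLIVA		970.46	970.54	486.24	486.28	2	1091.11
Fr42	GSASGAFVY		857.46	857.39	429.74	429.70	2	972.22
Fr43	HGPPPPSPYRSAAGRAAL		1800.90	1800.94	601.31	601.32	3	1297.22
Fr43	EAEPAEAA		786.37	786.34	394.19	394.18	2	898.75
Fr43	SIAGVAAFIG		904.48	904.50	453.25	453.26	2	1251
Fr43	YAAKMRK		866.54	866.48	434.28	434.25	2	1337.14
Fr43	DDLKGTF		794.38	794.38	398.20	398.20	2	1155.71
Fr43	GGVYGTSAR		866.50	866.42	434.26	434.22	2	722.22
Fr43	GSECMWFAS		1016.33	1016.37	509.17	509.19	2	923.33
Fr43	AGFSYFGESS		1050.45	1050.43	526.23	526.22	2	957
Fr43	DLLALRELDVACN		1443.77	1443.74	722.89	722.88	2	1167.69
Fr43	NGGDLPGAL		812.42	812.40	407.22	407.21	2	968.89
Fr43	ALLQQQAQMAAALPLPP		1759.90	1759.97	587.64	587.66	3	1299.41
Fr43	LTPCAVPE		828.43	828.41	415.22	415.21	2	1383.75
Fr43	ERTGRVAM		918.48	918.47	460.25	460.24	2	771.25
Fr43	LNCALK		660.43	660.36	331.22	331.19	2	1176.67
Fr43	GAAPTPPSPPPATKPSTPPKPPT		2190.15	2190.17	731.06	731.06	3	1558.69
Fr43	IECCLLFALV		1122.55	1122.58	562.28	562.30	2	1585
Fr43	PVGCLPK		712.40	712.39	357.21	357.20	2	1550
Fr43	DEDESSFGK		1012.47	1012.40	507.24	507.21	2	712.22
Fr43	GASPVTFVFT		1024.49	1024.52	513.25	513.27	2	1295
Fr43	AGDLGAYG		722.39	722.32	362.20	362.17	2	911.25
Fr43	RSARVRVGSTAT		1259.69	1259.71	630.85	630.86	2	665.83
Fr43	INNNKIITNL	Deamidated (N)@2	1156.65	1156.65	579.33	579.33	2	1323
Fr43	DAVEIWRVK		1114.58	1114.61	558.30	558.31	2	1488.89
Fr44	DEVIPGAL		812.43	812.43	407.22	407.22	2	1440
Fr44	DATFCGDLDDA		1141.54	1141.42	571.78	571.72	2	830
Fr44	PKPPALCN		838.47	838.44	420.24	420.23	2	1562.5
Fr44	PPNPPNPPN		942.56	942.46	472.29	472.24	2	1743.33
Fr44	TPALVSQLH		964.50	964.53	483.26	483.27	2	1195.56
Fr44	TMSDRFL		868.51	868.41	435.26	435.21	2	1160
Fr44	AAGAAPLL		682.44	682.40	342.23	342.21	2	1297.5
Fr44	LIKELDSN		930.62	930.50	466.32	466.26	2	1303.75
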
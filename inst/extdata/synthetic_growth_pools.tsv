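isoacceptor	mu2.5	mu1.6	mu1.07	mu0.7	mu0.4
Ala1B	1370	1133	818	643	596
Ala2	756	598	399	361	290
Arg2	1933	1692	1165	926	835
Arg3	877	753	513	424	355
Arg4	1562	1281	898	725	625
Arg5	808	654	480	361	340
Asn	1337	1138	731	577	569
Asp1	4591	4251	2927	2213	2018
Cys	1945	1569	1158	945	774
Gln1	1145	920	680	543	472
Gln2	1495	1331	871	789	666
Glu2	954	754	524	465	420
Gly1	1099	952	615	516	443
Gly2	383	314	223	196	169
Gly3	2557	1939	1358	1156	1027
His	481	451	286	230	209
Ile1	521	463	315	249	223
Ile2	674	565	366	316	271
Leu1	1104	950	646	505	436
Leu2	2350	2206	1439	1140	1086
Leu3	1425	1202	821	695	541
Leu4	889	752	527	473	382
Leu5	271	243	171	131	113
Lys	1632	1344	1042	850	751
Met	2337	2122	1316	1118	1043
Phe	1976	1513	1020	884	823
Pro1	1065	924	581	489	439
Pro2	2370	2107	1436	1130	1062
Pro3	191	173	111	86	76
Ser1	1465	1264	929	711	612
Ser2	2211	1926	1257	1162	915
Ser3	1038	906	616	480	403
Ser5	1604	1384	941	711	621
Thr1	2804	2270	1660	1284	1102
Thr2	1491	1279	862	647	647
Thr3	590	451	332	281	235
Thr4	897	769	533	409	389
Trp	531	450	291	248	205
Tyr1	729	599	424	355	277
Tyr2	516	447	317	270	223
Val1	1375	1183	869	707	567
Val2A	496	382	270	222	189
Val2B	1061	848	596	491	452
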
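isoacceptor	t0	t2	t7	t17	t32
Ala1B	1407	1407	1407	1407	1407
Ala2	715	715	715	715	715
Arg2	2004	2004	2004	2004	2004
Arg3	835	835	835	835	835
Arg4	1597	1597	1597	1597	1597
Arg5	804	804	804	804	804
Asn	1273	1273	1273	1273	1273
Asp1	4888	4888	4888	4888	4888
Cys	1958	1958	1958	1958	1958
Gln1	1114	1114	1114	1114	1114
Gln2	1552	1552	1552	1552	1552
Glu2	952	952	952	952	952
Gly1	1058	1058	1058	1058	1058
Gly2	384	384	384	384	384
Gly3	2449	2449	2449	2449	2449
His	497	497	497	497	497
Ile1	555	555	555	555	555
Ile2	637	637	637	637	637
Leu1	1113	1113	1113	1113	1113
Leu2	2452	2452	2452	2452	2452
Leu3	1383	1383	1383	1383	1383
Leu4	932	932	932	932	932
Leu5	286	286	286	286	286
Lys	1691	1691	1691	1691	1691
Met	2342	2342	2342	2342	2342
Phe	1877	1877	1877	1877	1877
Pro1	1052	1052	1052	1052	1052
Pro2	2484	2484	2484	2484	2484
Pro3	190	190	190	190	190
Ser1	1498	1498	1498	1498	1498
Ser2	2288	2288	2288	2288	2288
Ser3	1028	1028	1028	1028	1028
Ser5	1572	1572	1572	1572	1572
Thr1	2803	2803	2803	2803	2803
Thr2	1443	1443	1443	1443	1443
Thr3	552	552	552	552	552
Thr4	905	905	905	905	905
Trp	524	524	524	524	524
Tyr1	697	697	697	697	697
Tyr2	551	551	551	551	551
Val1	1418	1418	1418	1418	1418
Val2A	470	470	470	470	470
Val2B	1025	1025	1025	1025	1025
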
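isoacceptor	t0	t2	t7	t17	t32
Ala1B	0.972	1	0.991	0.537	0.974
Ala2	0.874	0.941	0.957	0.447	0.803
Arg2	0.935	0.853	0.85	0.55	0.999
Arg3	0.871	0.789	0.803	0.46	0.813
Arg4	0.991	1	0.959	0.55	0.92
Arg5	0.978	0.914	0.96	0.55	0.891
Asn	0.871	0.891	0.947	0.526	0.839
Asp1	0.961	0.908	1	0.478	1
Cys	0.894	0.835	0.812	0.455	0.969
Gln1	0.964	0.969	1	0.505	0.952
Gln2	0.91	0.865	0.961	0.512	0.836
Glu2	0.925	0.846	0.874	0.468	0.915
Gly1	0.901	0.883	0.836	0.519	0.955
Gly2	0.862	0.835	0.947	0.437	0.865
Gly3	0.93	0.961	0.959	0.525	0.864
His	0.914	0.957	0.96	0.453	0.918
Ile1	0.853	0.838	0.882	0.455	0.819
Ile2	0.975	0.934	0.982	0.491	1
Leu1	0.858	0.057	0.036	0.056	0.059
Leu2	0.963	0.035	0.071	0.058	0.054
Leu3	0.991	0.034	0.061	0.079	0.032
Leu4	0.957	0.067	0.037	0.053	0.032
Leu5	0.9	0.034	0.06	0.061	0.036
Lys	0.923	0.848	0.947	0.531	0.831
Met	0.883	0.928	0.896	0.475	0.848
Phe	0.909	0.894	0.92	0.476	0.947
Pro1	0.915	0.932	0.962	0.531	0.998
Pro2	0.913	0.939	0.879	0.489	0.989
Pro3	0.981	0.915	0.98	0.55	0.917
Ser1	0.876	0.916	0.961	0.51	0.891
Ser2	0.887	0.84	0.972	0.447	0.967
Ser3	0.857	0.858	0.875	0.499	0.942
Ser5	0.988	0.964	1	0.528	1
Thr1	0.86	0.79	0.871	0.508	0.865
Thr2	0.903	0.813	0.907	0.541	0.952
Thr3	0.872	0.793	0.801	0.444	0.906
Thr4	0.963	0.96	1	0.498	0.988
Trp	0.91	0.84	0.835	0.482	0.956
Tyr1	0.912	0.889	0.948	0.485	0.859
Tyr2	0.893	0.811	0.839	0.458	0.96
Val1	0.921	0.927	0.977	0.525	0.893
Val2A	0.949	0.942	0.937	0.474	0.986
Val2B	0.983	1	1	0.541	0.919
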
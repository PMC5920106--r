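label	x	y	z
Fp1	-0.289428	0.952054	-0.099120
Fpz	-0.008883	0.998745	-0.049285
Fp2	0.272523	0.956988	-0.099521
AF7	-0.544568	0.827485	-0.136801
AF3	-0.343916	0.922361	0.175989
AF4	0.340074	0.922709	0.181543
AF8	0.531558	0.835701	-0.138020
F7	-0.761639	0.628240	-0.158812
F5	-0.705684	0.693502	0.145135
F3	-0.541958	0.733934	0.409417
F1	-0.294033	0.754941	0.586182
Fz	-0.007464	0.764997	0.643991
F2	0.293278	0.761677	0.577786
F4	0.536390	0.746045	0.394590
F6	0.704207	0.696838	0.136045
F8	0.754151	0.636455	-0.161808
FT7	-0.924345	0.344154	-0.164755
FC5	-0.886676	0.396394	0.238069
FC3	-0.685025	0.437015	0.582888
FC1	-0.372435	0.449340	0.812026
FCz	-0.006957	0.456551	0.889670
FC2	0.362839	0.460035	0.810380
FC4	0.681413	0.445723	0.580523
FC6	0.882118	0.407705	0.235892
FT8	0.917442	0.360728	-0.167855
T7	-0.988906	0.003755	-0.148494
C5	-0.953041	0.030265	0.301324
C3	-0.735914	0.052206	0.675060
C1	-0.394932	0.067502	0.916227
Cz	-0.006611	0.073923	0.997242
C2	0.394855	0.072419	0.915885
C4	0.738219	0.060799	0.671816
C6	0.953648	0.041263	0.298081
T8	0.988236	0.015545	-0.152146
TP7	-0.938888	-0.324500	-0.114847
CP5	-0.892051	-0.334192	0.304238
CP3	-0.681716	-0.323627	0.656147
CP1	-0.365287	-0.309269	0.878020
CPz	-0.006511	-0.307115	0.951650
CP2	0.374335	-0.308068	0.874624
CP4	0.688205	-0.317972	0.652126
CP6	0.896355	-0.324197	0.302396
TP8	0.938609	-0.324358	-0.117491
P9	-0.714000	-0.553672	-0.428545
P7	-0.787950	-0.612441	-0.063647
P5	-0.724851	-0.636081	0.264559
P3	-0.552328	-0.638123	0.536407
P1	-0.293972	-0.636079	0.713431
Pz	-0.007018	-0.633222	0.773939
P2	0.302251	-0.627902	0.717205
P4	0.555316	-0.632516	0.539952
P6	0.719840	-0.641410	0.265373
P8	0.783882	-0.617479	-0.065183
P10	0.705203	-0.561901	-0.432384
PO3	-0.381513	-0.858549	0.342552
POz	-0.008443	-0.876399	0.481511
PO4	0.366592	-0.866825	0.337971
O1	-0.301660	-0.951919	0.053395
Oz	-0.009426	-0.993550	0.113004
O2	0.287450	-0.956305	0.053416
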
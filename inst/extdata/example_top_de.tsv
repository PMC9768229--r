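pirna_id	mean_tpm_a	mean_tpm_b	reference_log2fc
t00003531	164.3288	375.8126	1.193428
t00003529	162.3703	376.3698	1.212863
t00007113	70.77197	218.2707	1.624868
t00002797	217.5227	449.2671	1.046407
t00009382	63.55267	159.767	1.329945
t00003181	156.5043	429.1206	1.45518
t00009622	62.8674	154.8359	1.300356
t00001771	328.9762	665.1857	1.015774
t00007019	93.5032	199.6792	1.094596
t00004577	138.9869	291.0943	1.066538
t00006386	101.8349	219.3988	1.107324
t00002725	223.7737	457.7331	1.032466
t00007398	90.0843	190.3056	1.078971
t00007717	81.69437	186.3416	1.189641
t00007494	82.5236	193.57	1.229977
t00003368	565.937	0.01	-15.7884
t00021600	83.9834	19.8615	-2.08013
t00009149	174.2414	56.50243	-1.6247
t00018153	91.88513	30.786	-1.57756
t00017913	93.2936	30.3104	-1.62197
t00049445	42.74047	2.820867	-3.92139
t00101777	21.43303	0.300867	-6.15457
t00002003	601.4204	294.1466	-1.03184
t00031563	56.7441	14.91327	-1.92787
t00046072	40.0407	9.062367	-2.14351
t00001675	777.2703	275.9745	-1.49388
t00000321	3258.568	1070.809	-1.60554
t00000218	4432.379	1528.403	-1.53606
t00039624	43.03687	13.90583	-1.62988
t00024428	65.75667	26.38123	-1.31763
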
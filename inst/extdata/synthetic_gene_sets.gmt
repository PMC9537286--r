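HALLMARK_HEDGEHOG_SIGNALING	synthetic	GENE0008	GENE0014	GENE0031	GENE0036	GENE0045	GENE0057	GENE0070	GENE0084	GENE0089	GENE0099	GENE0104	GENE0140	GENE0143	GENE0160	GENE0165	GENE0178	GENE0190	GENE0193	GENE0227	GENE0229	GENE0253	GENE0286	GENE0313	GENE0316	GENE0334	GENE0342	GENE0343	GENE0377	GENE0379	GENE0394	GENE0403	GENE0408	GENE0422	GENE0425	GENE0466
HALLMARK_E2F_TARGETS	synthetic	GENE0009	GENE0015	GENE0024	GENE0030	GENE0037	GENE0050	GENE0051	GENE0061	GENE0072	GENE0074	GENE0079	GENE0080	GENE0083	GENE0097	GENE0101	GENE0109	GENE0116	GENE0127	GENE0129	GENE0132	GENE0152	GENE0163	GENE0189	GENE0192	GENE0199	GENE0203	GENE0210	GENE0213	GENE0221	GENE0234	GENE0235	GENE0239	GENE0245	GENE0249	GENE0260	GENE0262	GENE0274	GENE0296	GENE0297	GENE0305	GENE0315	GENE0323	GENE0330	GENE0340	GENE0354	GENE0356	GENE0366	GENE0367	GENE0385	GENE0398	GENE0399	GENE0405	GENE0411	GENE0448	GENE0459	GENE0468	GENE0470	GENE0473	GENE0477	GENE0493
HALLMARK_HYPOXIA	synthetic	GENE0001	GENE0005	GENE0012	GENE0038	GENE0041	GENE0049	GENE0052	GENE0055	GENE0059	GENE0071	GENE0085	GENE0086	GENE0087	GENE0111	GENE0124	GENE0126	GENE0136	GENE0151	GENE0158	GENE0169	GENE0228	GENE0254	GENE0256	GENE0278	GENE0292	GENE0299	GENE0303	GENE0345	GENE0365	GENE0370	GENE0382	GENE0386	GENE0388	GENE0391	GENE0393	GENE0400	GENE0409	GENE0413	GENE0487	GENE0491
HALLMARK_INFLAMMATORY_RESPONSE	synthetic	GENE0003	GENE0017	GENE0029	GENE0034	GENE0042	GENE0062	GENE0069	GENE0075	GENE0091	GENE0093	GENE0098	GENE0102	GENE0130	GENE0131	GENE0162	GENE0164	GENE0166	GENE0198	GENE0231	GENE0237	GENE0242	GENE0244	GENE0270	GENE0285	GENE0293	GENE0304	GENE0307	GENE0310	GENE0321	GENE0338	GENE0339	GENE0378	GENE0410	GENE0424	GENE0427	GENE0440	GENE0461	GENE0474	GENE0481	GENE0484
SIG_DNA_REPAIR_7	synthetic	GENE0076	GENE0209	GENE0219	GENE0236	GENE0263	GENE0275	GENE0282
SIG_RADIOSENS_11	synthetic	GENE0010	GENE0016	GENE0064	GENE0115	GENE0200	GENE0202	GENE0328	GENE0341	GENE0353	GENE0368	GENE0463
SIG_IMMUNE_12	synthetic	GENE0006	GENE0019	GENE0021	GENE0157	GENE0185	GENE0208	GENE0224	GENE0317	GENE0322	GENE0329	GENE0480	GENE0489
SIG_HYPOXIA_15	synthetic	GENE0026	GENE0027	GENE0039	GENE0096	GENE0173	GENE0211	GENE0212	GENE0223	GENE0300	GENE0319	GENE0360	GENE0392	GENE0429	GENE0439	GENE0442
SIG_RADIOSENS_31	synthetic	GENE0007	GENE0013	GENE0077	GENE0078	GENE0108	GENE0114	GENE0147	GENE0149	GENE0154	GENE0175	GENE0191	GENE0197	GENE0225	GENE0252	GENE0259	GENE0318	GENE0348	GENE0351	GENE0363	GENE0374	GENE0380	GENE0395	GENE0436	GENE0450	GENE0451	GENE0460	GENE0465	GENE0482	GENE0496	GENE0497	GENE0498
SIG_EMT_42	synthetic	GENE0047	GENE0054	GENE0066	GENE0068	GENE0073	GENE0103	GENE0122	GENE0133	GENE0134	GENE0135	GENE0138	GENE0144	GENE0145	GENE0155	GENE0167	GENE0172	GENE0176	GENE0186	GENE0204	GENE0232	GENE0247	GENE0251	GENE0266	GENE0271	GENE0272	GENE0298	GENE0311	GENE0320	GENE0350	GENE0352	GENE0359	GENE0369	GENE0372	GENE0375	GENE0390	GENE0415	GENE0479	GENE0483	GENE0485	GENE0492	GENE0494	GENE0495
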
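#Activity	sitting
#ActivityID	8
#Date-Time	2026-01-05 09:30:00
#Note	synthetic fixture in the public gait-database text dialect (not real subject data)
acc_rf_x	acc_rf_y	acc_rf_z	gyro_rf_x	gyro_rf_y	gyro_rf_z	acc_lf_x	acc_lf_y	acc_lf_z	gyro_lf_x	gyro_lf_y	gyro_lf_z	acc_rs_x	acc_rs_y	acc_rs_z	gyro_rs_x	gyro_rs_y	gyro_rs_z	acc_ls_x	acc_ls_y	acc_ls_z	gyro_ls_x	gyro_ls_y	gyro_ls_z	acc_rt_x	acc_rt_y	acc_rt_z	gyro_rt_x	gyro_rt_y	gyro_rt_z	acc_lt_x	acc_lt_y	acc_lt_z	gyro_lt_x	gyro_lt_y	gyro_lt_z	act
-183	-71	487	80	-472	-437	477	-344	-120	435	17	-83	307	-83	265	201	384	354	32	-242	-124	62	219	372	-68	158	244	-24	-315	-393	-443	373	109	195	331	421	8
-182	-68	487	77	-470	-440	477	-343	-123	435	18	-84	308	-83	264	201	387	351	35	-239	-127	64	216	371	-69	160	244	-22	-316	-393	-440	372	108	194	334	423	8
-182	-67	487	74	-467	-441	476	-344	-123	432	15	-87	311	-81	264	202	387	353	34	-238	-129	63	213	373	-68	157	242	-23	-318	-392	-441	371	105	192	336	422	8
-180	-66	489	71	-468	-441	478	-341	-123	435	12	-84	314	-81	265	203	388	356	32	-239	-130	64	211	375	-68	154	245	-24	-321	-390	-444	371	108	190	338	421	8
-177	-65	486	74	-466	-441	476	-338	-124	433	12	-82	313	-84	266	200	391	354	32	-241	-131	65	214	373	-68	151	242	-21	-322	-393	-441	372	107	190	339	420	8
-174	-62	489	75	-464	-440	474	-335	-126	432	10	-80	313	-83	268	198	392	357	30	-241	-129	65	212	371	-71	154	244	-18	-325	-393	-443	375	109	193	339	419	8
-177	-60	490	74	-463	-438	475	-332	-127	435	9	-80	314	-80	270	199	391	357	27	-240	-128	68	215	370	-69	152	247	-20	-324	-396	-445	378	107	192	340	418	8
-180	-58	487	75	-464	-436	473	-330	-129	433	9	-80	311	-77	269	200	394	354	29	-242	-130	67	214	370	-68	149	247	-22	-322	-398	-442	378	108	191	338	418	8
-179	-59	484	77	-462	-433	474	-328	-126	436	7	-78	309	-75	268	197	397	351	30	-245	-128	69	216	371	-71	146	248	-25	-319	-397	-441	376	107	191	336	421	8
-180	-62	481	75	-465	-431	476	-327	-125	435	5	-77	308	-75	269	198	394	349	32	-248	-131	66	217	373	-70	149	249	-23	-316	-395	-440	379	104	192	334	423	8
-180	-60	483	76	-465	-430	479	-325	-125	436	4	-79	307	-73	267	201	396	350	35	-251	-129	66	220	373	-68	149	248	-22	-316	-397	-442	380	104	189	334	425	8
-180	-62	482	79	-467	-432	480	-326	-122	435	7	-80	304	-75	270	198	395	349	33	-253	-129	69	222	371	-67	152	249	-19	-318	-394	-440	380	101	192	335	422	8
-179	-65	483	79	-465	-430	482	-327	-121	438	8	-77	303	-74	273	200	398	351	33	-255	-127	71	222	370	-67	153	247	-19	-315	-396	-438	383	104	190	333	419	8
-176	-66	480	76	-467	-428	481	-325	-123	440	10	-78	304	-72	272	200	397	348	36	-253	-126	69	220	370	-70	156	249	-17	-312	-393	-438	381	107	193	335	419	8
-174	-69	483	74	-470	-427	480	-323	-123	440	8	-78	306	-69	270	200	394	346	33	-252	-125	67	218	368	-72	159	252	-14	-311	-396	-439	384	109	191	332	419	8
-177	-69	486	72	-469	-429	480	-324	-126	439	9	-77	307	-67	273	202	391	349	32	-249	-124	67	218	371	-72	157	250	-14	-312	-399	-437	386	106	194	331	420	8
-180	-68	483	74	-466	-429	477	-327	-125	437	10	-75	310	-69	270	199	393	350	32	-249	-122	64	216	371	-69	156	248	-12	-314	-396	-438	383	103	191	331	423	8
-177	-67	485	77	-468	-432	477	-330	-127	434	9	-73	309	-67	269	196	394	349	30	-250	-120	67	215	369	-69	153	249	-12	-311	-399	-441	382	104	194	334	421	8
-175	-68	488	76	-465	-429	476	-330	-126	435	6	-74	309	-70	270	197	393	350	31	-248	-119	66	212	368	-72	153	250	-9	-309	-401	-439	381	101	193	331	422	8
-175	-65	488	77	-464	-431	474	-333	-125	438	9	-75	308	-68	272	197	395	347	31	-245	-116	63	210	370	-70	155	250	-8	-311	-403	-439	378	102	192	332	422	8
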
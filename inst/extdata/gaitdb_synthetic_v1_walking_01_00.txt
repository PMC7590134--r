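#Activity	walking
#ActivityID	1
#Date-Time	2026-01-05 09:30:00
#Note	synthetic fixture in the public gait-database text dialect (not real subject data)
acc_rf_x	acc_rf_y	acc_rf_z	gyro_rf_x	gyro_rf_y	gyro_rf_z	acc_lf_x	acc_lf_y	acc_lf_z	gyro_lf_x	gyro_lf_y	gyro_lf_z	acc_rs_x	acc_rs_y	acc_rs_z	gyro_rs_x	gyro_rs_y	gyro_rs_z	acc_ls_x	acc_ls_y	acc_ls_z	gyro_ls_x	gyro_ls_y	gyro_ls_z	acc_rt_x	acc_rt_y	acc_rt_z	gyro_rt_x	gyro_rt_y	gyro_rt_z	acc_lt_x	acc_lt_y	acc_lt_z	gyro_lt_x	gyro_lt_y	gyro_lt_z	act
-146	262	-213	-487	210	-2	-405	-68	-464	-97	-367	482	-72	279	-162	-176	244	415	-49	-155	449	-285	461	-136	-486	-25	381	132	-417	-235	-169	-371	405	-108	140	-487	1
-145	264	-211	-488	210	1	-407	-65	-466	-98	-364	485	-69	282	-159	-179	242	417	-52	-152	448	-283	459	-134	-484	-24	380	135	-416	-236	-172	-374	404	-109	140	-485	1
-143	267	-208	-489	212	-1	-406	-66	-463	-95	-366	483	-71	283	-160	-181	239	417	-54	-151	446	-283	457	-137	-482	-24	378	136	-413	-233	-169	-374	402	-107	139	-483	1
-145	270	-209	-492	214	-2	-405	-69	-462	-98	-363	483	-74	285	-161	-184	240	420	-51	-153	443	-286	460	-136	-484	-25	380	137	-412	-235	-166	-375	401	-109	137	-486	1
-146	270	-208	-491	213	-1	-403	-71	-464	-97	-364	483	-74	285	-159	-183	242	422	-51	-150	442	-286	457	-136	-486	-28	382	136	-412	-233	-166	-372	398	-108	137	-489	1
-149	268	-210	-494	212	-1	-402	-74	-461	-98	-361	481	-72	283	-156	-184	239	421	-49	-149	441	-284	455	-134	-487	-27	384	138	-413	-231	-167	-369	400	-110	139	-487	1
-147	266	-211	-496	209	-4	-399	-73	-460	-97	-363	478	-75	280	-156	-187	242	424	-47	-148	440	-287	458	-133	-484	-27	384	139	-415	-233	-164	-366	402	-109	136	-487	1
-150	265	-211	-494	210	-7	-401	-70	-460	-100	-361	481	-72	282	-153	-184	240	421	-50	-149	437	-284	459	-133	-486	-30	387	138	-416	-236	-163	-369	401	-106	139	-490	1
-149	263	-208	-497	212	-4	-400	-67	-460	-98	-359	478	-71	280	-154	-187	240	421	-53	-152	435	-287	461	-134	-486	-29	384	139	-418	-239	-163	-368	401	-104	142	-492	1
-152	261	-208	-497	212	-1	-398	-66	-459	-95	-356	478	-68	280	-156	-185	242	418	-50	-151	432	-290	458	-136	-488	-28	387	138	-416	-236	-164	-368	402	-106	144	-492	1
-152	262	-211	-499	213	0	-397	-65	-460	-96	-357	478	-68	282	-156	-185	245	417	-52	-148	432	-291	460	-133	-486	-28	386	141	-419	-236	-162	-371	400	-103	145	-494	1
-155	264	-209	-502	211	1	-396	-67	-459	-96	-359	477	-69	279	-153	-182	247	418	-54	-148	433	-291	458	-134	-486	-25	383	141	-419	-234	-164	-372	397	-102	146	-496	1
-155	262	-206	-503	212	-1	-399	-69	-460	-96	-360	474	-71	278	-156	-184	245	418	-54	-145	436	-293	459	-131	-487	-23	382	143	-420	-236	-162	-373	399	-104	149	-498	1
-154	262	-208	-502	214	2	-402	-69	-459	-93	-361	473	-74	279	-159	-186	248	418	-54	-145	438	-290	458	-130	-488	-21	385	142	-419	-236	-159	-374	396	-102	147	-501	1
-154	260	-208	-501	216	2	-400	-67	-462	-96	-360	470	-76	281	-160	-184	251	415	-52	-148	440	-292	461	-131	-485	-22	382	144	-420	-233	-160	-374	397	-105	146	-503	1
-156	259	-209	-503	218	2	-401	-66	-462	-98	-363	469	-73	280	-159	-184	253	417	-50	-150	437	-289	458	-133	-482	-20	381	142	-417	-236	-162	-376	399	-108	146	-501	1
-153	261	-206	-502	218	-1	-399	-65	-465	-97	-364	471	-76	279	-161	-186	254	416	-52	-149	437	-290	455	-130	-484	-20	383	145	-420	-234	-159	-378	397	-108	145	-501	1
-150	261	-209	-500	220	1	-400	-65	-462	-97	-363	474	-77	278	-160	-186	251	419	-49	-146	440	-290	454	-130	-487	-17	385	144	-418	-237	-157	-377	395	-109	145	-503	1
-152	260	-211	-501	223	2	-401	-63	-463	-96	-365	471	-80	278	-161	-187	250	422	-50	-144	443	-290	456	-130	-489	-19	385	146	-421	-240	-157	-379	393	-110	145	-505	1
-152	262	-209	-498	224	5	-400	-66	-465	-99	-367	474	-79	275	-164	-188	248	420	-48	-142	444	-293	459	-130	-490	-20	384	145	-421	-237	-155	-381	396	-110	146	-505	1
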
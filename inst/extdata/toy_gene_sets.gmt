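osteoblast_program	toy synthetic gene set	G0301	G0302	G0303	G0304	G0305	G0306	G0307	G0308	G0309	G0310	G0311	G0312	G0313	G0314	G0315	G0316	G0317	G0318	G0319	G0320	G0321	G0322	G0323	G0324	G0325	G0326	G0327	G0328	G0329	G0330
chondrocyte_program	toy synthetic gene set	G0401	G0402	G0403	G0404	G0405	G0406	G0407	G0408	G0409	G0410	G0411	G0412	G0413	G0414	G0415	G0416	G0417	G0418	G0419	G0420	G0421	G0422	G0423	G0424	G0425	G0426	G0427	G0428	G0429	G0430
hypertrophic_chondrocyte	toy synthetic gene set	G0451	G0452	G0453	G0454	G0455	G0456	G0457	G0458	G0459	G0460	G0461	G0462	G0463	G0464	G0465	G0466	G0467	G0468	G0469	G0470	G0471	G0472	G0473	G0474	G0475	G0476	G0477	G0478	G0479	G0480
immune_interaction	toy synthetic gene set	G0501	G0502	G0503	G0504	G0505	G0506	G0507	G0508	G0509	G0510	G0511	G0512	G0513	G0514	G0515	G0516	G0517	G0518	G0519	G0520	G0521	G0522	G0523	G0524	G0525	G0526	G0527	G0528	G0529	G0530
cell_cycle_checkpoint	toy synthetic gene set	G0601	G0602	G0603	G0604	G0605	G0606	G0607	G0608	G0609	G0610	G0611	G0612	G0613	G0614	G0615	G0616	G0617	G0618	G0619	G0620	G0621	G0622	G0623	G0624	G0625	G0626	G0627	G0628	G0629	G0630
scattered_control	toy synthetic gene set	G0700	G0740	G0780	G0820	G0860	G0900	G0940	G0980	G1020	G1060	G1100	G1140	G1180	G1220	G1260	G1300	G1340	G1380	G1420	G1460	G1500	G1540	G1580	G1620	G1660	G1700	G1740	G1780	G1820	G1860
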
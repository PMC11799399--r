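protein	sequence	mz_maldi	mascot_ppm	mascot_score	mz_lc	ppm_diff_printed	lc_charge	mobility_maldi	mobility_lc	mobility_diff_printed	b_detected	b_total	y_detected	y_total	tissue
Collagen 1A1	GVVGLP[16]GQR	898.5029	2.8	38.6	898.5035	-0.67	1	1.4247	1.4167	0.008	3	8	7	8	PDX tumor
Histone H2A type 1-B/E	AGLQFPVGR	944.5373	2.4	34.27	944.5239	14.19	1	1.4714	1.4676	0.0038	1	8	8	8	PDX tumor
Histone 4	DNIQGITKPAIR	1325.7528	2.3	89.94	1325.7487	3.09	1	1.77	1.7707	-0.0007	1	11	11	11	PDX tumor
Collagen 1A1	GSAGPPGATGFP[16]GAAGR	1443.6980	19.1	43.3	1443.6866	7.90	1	1.7822	1.7857	-0.0035	5	16	12	16	PDX tumor
Collagen 1A1	GPAGPQGPR	836.4425	6.1	52.67	NA	NA	NA	1.3255	NA	NA	4	8	8	8	Mouse kidney
Collagen 1A1	GVQGPP[16]GPAGPR	1105.5731	2.4	39.07	1105.5647	7.60	1	1.5468	1.5854	-0.0386	7	11	10	11	Mouse kidney
Actin A	AVFPSIVGRPR	1198.7003	3.0	28.92	1198.7029	-2.17	2	1.6947	0.9633	NA	4	10	8	10	Mouse kidney
Collagen 1A2	GIP[16]GPAGAAGATGAR	1239.6418	1.6	28.8	1239.6357	4.92	1	1.7107	1.7408	-0.0301	7	14	12	14	Mouse kidney
Collagen 1A1	GAAGPP[16]GATGFP[16]GAAGR	1443.6943	1.9	23.84	1443.6807	9.42	1	1.7412	1.758	-0.0168	8	16	12	16	Mouse kidney
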
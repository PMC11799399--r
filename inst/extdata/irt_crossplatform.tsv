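sequence	mz_lc	mz_maldi	ppm_error_printed	mobility_lc	mobility_maldi	mobility_delta_printed
LGGNEQVTR	973.5061	973.5055	-0.616	1.443	1.434	0.009
GTFIIDPGGVIR	1244.6997	1244.6981	-1.285	1.739	1.745	0.006
TPVISGGPYEYR	1338.6688	1338.6705	1.270	1.755	1.751	0.004
TPVITGAPYEYR	1366.7000	1366.6939	-4.463	1.777	1.772	0.005
DGLDAASYYAPVR	1397.6695	1397.6699	0.286	1.791	1.789	0.002
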
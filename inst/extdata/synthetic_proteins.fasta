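>COL1_SYN synthetic collagen-like test protein
LFGAPPGPLGKAPPLGGAAERAFGSLLQLAGPAFGAPRGFAVAGGFPVQEQFSARGGAQGPGGLGEAPRSEPVSGEGVQPVEFFQRLFPPAGPRGAAPPFFSFPPGRAALPGPPAGGLPPPSGKSGAPGLGGSGLGRGLGEPAGLQVGSPEVREQGVASGPVFPGRVLPVFLQQPGPFPSPGKFPPGFLLPSESPK
>HIST_SYN synthetic histone-like test protein
GISVLGLFAVIGINISRLVYVAVGNSFIRQAELANVAIRFAFIVFGAQTALKFVSIQTFYRNYNAGVIFQNSFGAVLKGVYVGLVRAGTDTADNIVLVGSGFK
>ACTB_SYN synthetic actin-like test protein
FTDSIQVKIMLNSGSLEDRTMTIGISDMFLLKITIYMHFLSDEFRTHWLLHQSQKHVATYYIWLYHIQRDDWVMNAGGINIELRGLSNSFYLK
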
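pair,varied,protac_id,protac_log_s,protac_censored,bb_id,bb_log_s,bb_censor
warhead_pair,warhead,MZ1,-4.42,FALSE,JQ1-carboxylic-acid,-2.6,above
warhead_pair,warhead,MZP-54,-6.29,FALSE,I-BET726,-4.42,none
linker_pair,linker,dBET57,-4.52,FALSE,ethylamine-linker,,none
linker_pair,linker,ZXH-3-26,-5.53,FALSE,pentylamine-linker,,none
e3_pair,e3_ligand,BI-3663,-5.16,FALSE,pomalidomide,-4.44,none
e3_pair,e3_ligand,BI-0319,-5.58,FALSE,SRS-AHPC-HCl,-2.68,none
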
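quantity	reads
clean_reads_saliva	79816837
clean_reads_fecal	282771421
clean_reads_total	362588258
species_annotated_reads	243325739
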
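# Printed replicon summary of the C. necator NH9 complete genome
# (accessions CP017757-CP017760): per-replicon length, GC percent and
# annotated CDS count, as published with the assembly.
replicon	accession	length_bp	gc_percent	cds_count
chromosome_1	CP017757	4347557	65.8	3912
chromosome_2	CP017758	3395604	65.5	2932
pENH91	CP017760	77172	64.2	78
pENH92	CP017759	426602	61.8	368
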
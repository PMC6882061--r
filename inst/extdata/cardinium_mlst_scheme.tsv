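primer_name	sequence	role	locus	tm_c	gene_length	amp_start	amp_end	fragment_size
gyrb_859F	ATGCAYGTMACBGGDTTTARAAG	forward	gyrB	50	1950	859	1637	736
gyrb_1637R	TARAGTGGRGGRGARGCAAT	reverse	gyrB	50	1950	859	1637	736
groel_346F	VTHAARCGBGGBATWGACAA	forward	groEL	52	1638	346	842	476
groel_287F	CNCARKCTATWTTYRYVCATGG	alt_forward	groEL	52	1638	346	842	476
groel_842R	TTGGBGAYAGAAGRAARGCNATG	reverse	groEL	52	1638	346	842	476
sufb_806F	CTACNGTDCARAATTGGTATCC	forward	sufB	50	1443	806	1289	451
sufb_1289R	ADYTGRTCYKCRCTRATTTT	reverse	sufB	50	1443	806	1289	451
EF_1162F	GCNGTRGTIGGITTTAARGARATTA	forward	EF-G	52	2142	1162	1689	482
EF_1689R	AAABCCYTTYTGAATIGCTGG	reverse	EF-G	52	2142	1162	1689	482
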
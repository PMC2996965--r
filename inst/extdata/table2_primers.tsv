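# Allele-specific primer panel as published (bold markup dropped on transcription).
# label keeps the printed discrimination suffix; coordinates are 1-based inclusive
# positions on the reference alignment, start > end for reverse primers as printed.
# Three rows (F4, F5, F6 a/t) have span 19 but a printed 18-mer sequence: the
# published table evidently lost one character in those rows; they are kept
# verbatim and flagged by read_primer_table().
label	orientation	sequence	ref_start	ref_end
F1 c/t	forward	GARMGAGTGTCRTTTCTY	13	30
F2 c/t	forward	GAGTGTCRTTTCTYAAAY	17	34
F3 g/c	forward	TTTCTYAAAYGGGACS	25	40
F4 ac	forward	GGACSGAGAGGGTGCGGC	35	53
F5 ct	forward	GGACSGAGCGGGTGCGGT	35	53
F6 a/t	forward	GACSGAGMGGGTGCGGYW	36	54
F6 a/c	forward	GGGTGCGGYWSCTGGAM	45	61
F7 a/t/c	forward	CTGGAMAGATACTWCH	56	71
F8 a/t	forward	HMTAAYGGAGAAGAGW	71	86
F9 a/t/c	forward	HMTAAYGGAGAAGAGWH	71	87
F10 a/g	forward	GACTGGGGCGAGTWYCGR	104	121
F11 g/c	forward	TGGAACAGCCAGAAGGGAS	158	176
R1 g/a/t	reverse	CTTCTGGCTGTTCCAD	172	157
R2 a/g	reverse	CTTCTGGCTGTTCCADTR	172	155
R3 c/t	reverse	CTGGCTGTTCCADTRCTY	169	152
R4 ct	reverse	CTGTTCCADTRGTYRGCKCT	165	146
R5 tc	reverse	CTGTTCCADTRGTYRGCKTC	165	146
R6 g/a/c	reverse	CTGCAGTACGTGTCCACV	216	199
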
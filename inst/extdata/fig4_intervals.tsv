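label	location	genetic_mu	physical_mb
kar-cv-c	86E	2.4	1.75
su_wa-pn	2A	NA	1.16
rux-cm	6E	5	1.6
mal-su_f	20C	1.1	2.2
chr4_euchromatin	102D	NA	1.35
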
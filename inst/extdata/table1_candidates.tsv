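gene	shr	jh	my	tp	tail_phenotype
Crispld1	TRUE	FALSE	TRUE	TRUE	FALSE
Cyp26a1	FALSE	FALSE	FALSE	FALSE	TRUE
Fgfr3	FALSE	FALSE	FALSE	TRUE	TRUE
Hoxc13	FALSE	FALSE	FALSE	FALSE	TRUE
Ihh	FALSE	TRUE	TRUE	TRUE	TRUE
Lmcd1	FALSE	TRUE	TRUE	TRUE	FALSE
Nkx3-2	FALSE	FALSE	FALSE	FALSE	TRUE
Nlgn3	FALSE	TRUE	TRUE	TRUE	FALSE
Npr3	TRUE	TRUE	TRUE	TRUE	TRUE
Pappa2	FALSE	TRUE	FALSE	FALSE	TRUE
Phex	FALSE	FALSE	TRUE	FALSE	TRUE
Prickle1	FALSE	TRUE	FALSE	FALSE	TRUE
Ror2	FALSE	FALSE	FALSE	FALSE	TRUE
Sox5	TRUE	FALSE	FALSE	FALSE	TRUE
Sox9	FALSE	FALSE	FALSE	FALSE	TRUE
Thra	FALSE	TRUE	FALSE	FALSE	TRUE
Ttll9	FALSE	TRUE	TRUE	TRUE	FALSE
Twsg1	FALSE	FALSE	FALSE	FALSE	TRUE
Wnt4	TRUE	FALSE	TRUE	TRUE	FALSE
Zim1	FALSE	TRUE	TRUE	TRUE	FALSE
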
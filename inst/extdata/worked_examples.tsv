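id	figure	gene	sequence	mods	charge	printed_mz	printed_ppm_error	protein_sites	note
galphat1_E167_D169	Fig1	Gnat1	LVTPGYVPTEQDVLR	Arg (DE)@10	3	615.0073	-0.3	E167|D169	site ambiguous between E167 and D169; either placement is isobaric
gbeta1_E12	Fig3A	Gnb1	SELDQLRQEAEQLK	Acetyl (Protein N-term)@0;Arg (DE)@11	3	628.9973	0.4	E12	protein N-terminal peptide, acetylated
gbeta1_D27	Fig3B	Gnb1	ACADATLSQITNNIDPVGR	Carbamidomethyl (C)@2;MethylArg (DE)@4	3	729.3709	-4	D27	monomethyl-arginylated
rgs6_D15	Fig5A	Rgs6	GIADPEESSPNMIVYCK	Carbamidomethyl (C)@16;MethylArg (DE)@4	2	1040.4955	-5	D15	monomethyl-arginylated
rgs7_E73_D74_E77	Fig5B	Rgs7		DimethylArg (DE)	2	791.9492	2	E73|D74|E77	sequence not recoverable from the published text (capped residues typeset as graphics); printed precursor and sites only
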
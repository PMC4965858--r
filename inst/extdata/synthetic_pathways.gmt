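glycine_serine_metabolism_synthetic	synthetic stand-in for an amino-acid metabolism pathway	GLDC	PSAT	PYCR2	ASNS	SHMT2	PHGDH
dna_mismatch_repair_synthetic	synthetic stand-in for a DNA repair pathway	MSH6	MSH2	MLH1	PCNA	TOP2A	CDKN2A
antigen_presentation_synthetic	synthetic stand-in for an antigen processing pathway	HLA-B	HLA-C	HLA-DRB1	TAP1	B2M
cholesterol_biosynthesis_synthetic	synthetic stand-in for a sterol biosynthesis pathway	FDFT1	HMGCR	SQLE	LSS	DHCR7
cytoskeleton_adhesion_synthetic	synthetic stand-in for a cell adhesion pathway	PPL	EVPL	PLEC	SPTA1	LAMA5	LAMC2	COL12A1
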
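cdr3	v.segm	j.segm	antigen.epitope	antigen.species	note
CASSIRSSYEQYF	TRBV19*01	TRBJ2-7*01	GILGFVFTL	InfluenzaA	synthetic
CASSIRSAYEQYF	TRBV19*01	TRBJ2-7*01	GILGFVFTL	InfluenzaA	synthetic
CASSLGQAYEQYF	TRBV27*01	TRBJ2-7*01	GLCTLVAML	EBV	synthetic
CASSQTGTGELFF	TRBV6-2*01	TRBJ2-2*01	GLCTLVAML	EBV	synthetic
CASSPQRNTEAFF	TRBV28*01	TRBJ1-1*01	NLVPMVATV	CMV	synthetic
CASSPVTGGIYGYTF	TRBV28*01	TRBJ1-2*01	NLVPMVATV	CMV	synthetic
CASSLAPGTTNEKLFF	TRBV5-1*01	TRBJ1-4*01	NLVPMVATV	CMV	synthetic
CASTPGDEQFF	TRBV19*01	TRBJ2-1*01	IPSINVHHY	CMV	synthetic
CASSSANYGYTF	TRBV7-9*01	TRBJ1-2*01	TPRVTGGGAM	CMV	synthetic
CASGLAGGRNEQFF	TRBV6-2*01	TRBJ2-1*01	RAKFKQLL	EBV	synthetic
CASSPGQGNTEAFF	TRBV27*01	TRBJ1-1*01	RAKFKQLL	EBV	synthetic
CASNRDRGRYGYTF	TRBV5-1*01	TRBJ1-2*01	YVLDHLIVV	EBV	synthetic
CASSEARGGVEKLFF	TRBV19*01	TRBJ1-4*01	YVLDHLIVV	EBV	synthetic
CASSYSTGDEQYF	TRBV6-2*01	TRBJ2-7*01	YLQPRTFLL	SARS-CoV-2	synthetic
CASRPDIEAFF	TRBV28*01	TRBJ1-1*01	YLQPRTFLL	SARS-CoV-2	synthetic
CASSLEGQGYEQYF	TRBV7-9*01	TRBJ2-7*01	YLQPRTFLL	SARS-CoV-2	synthetic
CAWSVGVGQPQHF	TRBV30*01	TRBJ1-5*01	KLGGALQAK	CMV	synthetic
CASSDRDRVNTEAFF	TRBV6-2*01	TRBJ1-1*01	KLGGALQAK	CMV	synthetic
CASSFGREDTQYF	TRBV27*01	TRBJ2-3*01	ELAGIGILTV	HomoSapiens	synthetic
CASSAGQGVYGYTF	TRBV9*01	TRBJ1-2*01	ELAGIGILTV	HomoSapiens	synthetic
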
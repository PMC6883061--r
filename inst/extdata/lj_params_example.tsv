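residue	atom	epsilon	rmin_half
ALA	CA	0.20	2.10
GLU	CB	0.21	2.30
ASP	CB	0.21	2.25
LYS	CB	0.18	2.35
*	C	0.10	2.00
*	N	0.17	1.85
*	O	0.12	1.70
*	S	0.25	2.00
*	H	0.03	0.60
*	AU	0.10	1.66
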
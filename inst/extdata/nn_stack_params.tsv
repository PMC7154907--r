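# RNA-RNA nearest-neighbor helix parameters (Turner rules).
# stack rows: top = 5'->3' dinucleotide, bottom = 3'->5' dinucleotide;
#   top[1] pairs bottom[1], top[2] pairs bottom[2] (WC or G.U wobble).
# Watson-Crick stacks: Xia et al. (1998) Biochemistry 37:14719 (dH, dS, dG37).
# G.U wobble stacks: Turner & Mathews 2004 set (dG37, dH; dS derived).
# init: duplex initiation; terminal_au: per terminal A.U or G.U pair penalty.
# Units: dH kcal/mol, dS cal/(mol K), dG37 kcal/mol.
kind	top	bottom	dH_kcal	dS_cal	dG37_kcal
stack	CG	GC	-10.64	-26.7	-2.36
stack	CC	GG	-13.39	-32.7	-3.26
stack	CU	GG	-12.1	-32.2	-2.1
stack	CG	GU	-5.6	-13.5	-1.4
stack	CU	GA	-10.48	-27.1	-2.08
stack	CA	GU	-10.44	-26.9	-2.11
stack	GG	CC	-13.39	-32.7	-3.26
stack	GC	CG	-14.88	-36.9	-3.42
stack	GU	CG	-12.6	-32.6	-2.5
stack	GG	CU	-8.3	-21.9	-1.5
stack	GU	CA	-11.4	-29.5	-2.24
stack	GA	CU	-12.44	-32.5	-2.35
stack	GG	UC	-12.1	-32.2	-2.1
stack	GC	UG	-12.6	-32.6	-2.5
stack	GU	UG	-14.6	-51.3	1.3
stack	GG	UU	-13.5	-41.9	-0.5
stack	GU	UA	-8.8	-23.9	-1.4
stack	GA	UU	-12.8	-37.1	-1.3
stack	UG	GC	-5.6	-13.5	-1.4
stack	UC	GG	-8.3	-21.9	-1.5
stack	UU	GG	-13.5	-41.9	-0.5
stack	UG	GU	-9.3	-31	0.3
stack	UU	GA	-3.2	-8.4	-0.6
stack	UA	GU	-7	-19.3	-1
stack	AG	UC	-10.48	-27.1	-2.08
stack	AC	UG	-11.4	-29.5	-2.24
stack	AU	UG	-8.8	-23.9	-1.4
stack	AG	UU	-3.2	-8.4	-0.6
stack	AU	UA	-9.38	-26.7	-1.1
stack	AA	UU	-6.82	-19	-0.93
stack	UG	AC	-10.44	-26.9	-2.11
stack	UC	AG	-12.44	-32.5	-2.35
stack	UU	AG	-12.8	-37.1	-1.3
stack	UG	AU	-7	-19.3	-1
stack	UU	AA	-6.82	-19	-0.93
stack	UA	AU	-7.69	-20.5	-1.33
init			3.61	-1.5	4.09
terminal_au			3.72	10.5	0.45
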
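# Nearest-neighbor helix stacking free energies for RNA duplexes, 37 C, 1 M NaCl.
# Published Turner-rules parameters: Watson-Crick stacks from Xia et al. (1998)
# Biochemistry 37:14719; G.U wobble stacks from Mathews et al. (1999) JMB 288:911,
# as tabulated in the Turner 2004 set (rounded to 0.1 kcal/mol).
# A stack is two consecutive base pairs read 5'->3' on the top strand:
# pair1 = (top_i, bottom_i), pair2 = (top_i+1, bottom_i+1); dg37 in kcal/mol.
# Duplex initiation +4.10; terminal AU or GU penalty +0.50 per helix end;
# self-complementary duplex symmetry correction +0.43 (Xia et al. 1998).
pair1	pair2	dg37
AU	AU	-0.90
UA	AU	-1.30
CG	AU	-2.10
GC	AU	-2.40
GU	AU	-1.30
UG	AU	-1.00
AU	UA	-1.10
UA	UA	-0.90
CG	UA	-2.10
GC	UA	-2.20
GU	UA	-1.40
UG	UA	-0.60
AU	CG	-2.20
UA	CG	-2.40
CG	CG	-3.30
GC	CG	-3.40
GU	CG	-2.50
UG	CG	-1.50
AU	GC	-2.10
UA	GC	-2.10
CG	GC	-2.40
GC	GC	-3.30
GU	GC	-2.10
UG	GC	-1.40
AU	GU	-0.60
UA	GU	-1.00
CG	GU	-1.40
GC	GU	-1.50
GU	GU	-0.50
UG	GU	0.30
AU	UG	-1.40
UA	UG	-1.30
CG	UG	-2.10
GC	UG	-2.50
GU	UG	1.30
UG	UG	-0.50
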
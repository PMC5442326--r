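# Base-pair classification patterns: donor-atom/acceptor-atom pairs per
# geometry class. A pair is assigned a class when at least `min_bonds` of
# the class's patterns are matched by detected hydrogen bonds between the
# two residues (reciprocal symmetric bonds count individually).
# base letters: G, A, C, T, I (hypoxanthine)
class	base_d	donor	base_a	acceptor	min_bonds
WC_GC	G	N1	C	N3	2
WC_GC	G	N2	C	O2	2
WC_GC	C	N4	G	O6	2
GG_N1_CARBONYL	G	N1	G	O6	2
GA_N1N7_CARBONYLAMINO	G	N1	A	N7	2
GA_N1N7_CARBONYLAMINO	A	N6	G	O6	2
G_I_HOOGSTEEN	G	N1	I	N7	2
G_I_HOOGSTEEN	G	N2	I	O6	2
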
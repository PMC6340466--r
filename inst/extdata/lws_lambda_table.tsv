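# LWS/MWS lambda-max lookup over the five-site haplotype
# (bovine rhodopsin numbering: sites 180, 197, 277, 285, 308).
# type=exact rows are pinned published assignments and take precedence;
# type=shift rows are additive spectral shifts (nm) relative to the base
# haplotype, used only as fallback for haplotypes without an exact entry.
type	key	nm
base	SHYTA	560
exact	SHYTA	560
exact	AHYTA	555
exact	SHYAA	543
exact	AHYAA	536
shift	S180A	-5
shift	H197Y	-28
shift	Y277F	-8
shift	T285A	-17
shift	A308S	-27
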
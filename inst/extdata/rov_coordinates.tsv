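node	label	kind	x	y	z	radius
RSFGmed	RSFGmed	functional	9	51	39	10
LANG_f	LANG	functional	-42	-54	24	10
LIFGoperc	LIFGoperc	functional	-54	18	18	10
RSTG	RSTG	functional	54	-24	15	10
LPCUN	LPCUN	functional	-3	-60	36	10
LSTG	LSTG	functional	-39	-36	12	10
LSFGdor	LSFGdor	structural	-20	16	45	10
RIFGtriang	RIFGtriang	structural	39	18	27	10
LIFGtriang	LIFGtriang	structural	-36	15	27	10
LANG_s	LANG	structural	-39	-57	30	10
RANG	RANG	structural	45	-48	27	10
RPreCG	RPreCG	structural	18	-18	66	10
RCAU	RCAU	structural	15	6	21	10
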
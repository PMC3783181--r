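# Default selective constraints on codon-anticodon coupling (s-values),
# one per wobble pairing kind. Watson-Crick pairings carry no penalty.
A34:U3 = 0
G34:C3 = 0
U34:A3 = 0
C34:G3 = 0
G34:U3 = 0.41
I34:C3 = 0.28
I34:A3 = 0.9999
U34:G3 = 0.68
L34:A3 = 0.89
# Per-interaction override (codon:anticodon): the generic inosine:A
# constraint leaves CGA two orders of magnitude slower than any other
# codon and dominates every statistic; a retuned value matches
# experimental elongation data better.
CGA:ACG = 0.9172
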
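# Example relative-adaptiveness weights for CAI, derived from
# the bundled synthetic growth-rate reference pool (per synonymous
# family, preferred codon = 1). CAI is reference-set dependent:
# substitute weights from your own highly-expressed gene set.
codon	weight
AAA	1
AAC	1
AAG	0.32
AAU	0.59
ACA	0.2643
ACC	1
ACG	0.5239
ACU	0.59
AGA	0.8081
AGC	0.3873
AGG	0.6766
AGU	0.2285
AUA	0.1423
AUC	1
AUG	1
AUU	0.59
CAA	0.6151
CAC	1
CAG	1
CAU	0.59
CCA	0.0806
CCC	1
CCG	0.4752
CCU	0.59
CGA	0.0828
CGC	0.72
CGG	0.4537
CGU	1
CUA	0.6064
CUC	1
CUG	0.6638
CUU	0.59
GAA	1
GAC	1
GAG	0.32
GAU	0.59
GCA	1
GCC	0.5518
GCG	0.32
GCU	0.3256
GGA	0.1498
GGC	1
GGG	0.4777
GGU	0.59
GUA	0.8831
GUC	1
GUG	0.2826
GUU	0.59
UAC	1
UAU	0.59
UCA	0.5467
UCC	0.5986
UCG	1
UCU	0.3531
UGC	1
UGG	1
UGU	0.59
UUA	0.1153
UUC	1
UUG	0.4152
UUU	0.59
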
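# Raf signalling pathway gold-standard network.
# Transcribed from the currently accepted consensus signalling network of
# Sachs et al. (2005), Science 308:523-529 (flow-cytometry study of human
# primary T cells): 11 phosphoproteins/phospholipids, 20 directed edges.
# Arrows point in the direction of signal transduction.
parent	child
PIP3	PLCg
PIP3	PIP2
PIP3	Akt
PLCg	PIP2
PLCg	PKC
PIP2	PKC
PKC	PKA
PKC	Raf
PKC	Mek
PKC	Jnk
PKC	P38
PKA	Raf
PKA	Mek
PKA	Erk
PKA	Akt
PKA	Jnk
PKA	P38
Raf	Mek
Mek	Erk
Erk	Akt
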
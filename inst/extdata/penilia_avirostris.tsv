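taxon	sequence	absent	note
Penilia_avirostris	F-J,B-G-H-M,A,D-K-L-N-S,I,C-P-Q-R-T-U-X-Z,O,V,Y,AA	E,W	Stage anchors: F-J at E III; B-G-H-M at E IV; D-K-L-N-S at L V; C-P-Q-R-T-U-X-Z at L VI. Placements of G, M, N and D are judgment calls where the staged descriptions are ambiguous.
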
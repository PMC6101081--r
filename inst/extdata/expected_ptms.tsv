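name	monoisotopic_mass	residues
Acetylation	42.01056	R,K
Methylation	14.01565	R,K
Dimethylation	28.03130	R,K
Trimethylation	42.04695	R
Phosphorylation	79.96633	S,T,Y
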
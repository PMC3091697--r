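# Demonstration motif file: name TAB IUPAC consensus, one binding-site
# variant per line. These are synthetic fixture patterns for examples and
# tests, not curated database motifs. "MRE" is an MRE-like consensus
# (fixture-only), "HNF4A" an HNF4A-like direct repeat, "FOXL1" a
# forkhead-like core.
HNF4A	RGGNCAAAGGTCA
MRE	TGCRCNCGGCCC
FOXL1	RYMAAYA
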
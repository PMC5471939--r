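start,end,category,section
0,114,element count,Hierarchic element counts
115,262,ring system,Rings (ESSSR ring set: counts and ring types)
263,326,atom pair,Simple atom pairs
327,415,nearest neighbor,Simple atom nearest neighbors
416,459,nearest neighbor,Detailed atom neighborhoods
460,712,SMARTS pattern,Simple SMARTS patterns
713,880,SMARTS pattern,Complex SMARTS patterns
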
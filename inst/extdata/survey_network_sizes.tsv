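network	n_nodes	n_edges
Grassland	117	663
Farmland	102	306
Wetland	154	684
Sea buckthorn forest	93	297
Spring	150	695
Summer	151	611
Autumn	147	688
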
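name	note
dinucleotide_binding_motif	NAD(P)-binding region conserved across plant lycopene beta-cyclases
cyclase_motif_I	cyclase motif I
cyclase_motif_II	cyclase motif II
conserved_region_beta_LYC	region conserved specifically in beta-cyclases
beta_cyclase_motif	beta-cyclase diagnostic motif
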
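ligand,dE_vdW,dE_Coul,ddG_PB,ddG_SA,minus_TdS,dG_bind_printed
TBTOH,-184.022,-18.402,115.953,-21.718,29.804,-78.385
TPTOH,-195.024,-1.941,105.751,-21.482,21.963,-90.732
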
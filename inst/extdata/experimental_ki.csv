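ligand,Ki_molar,temperature_K,dG_exp_printed
TBTOH,50e-6,310,-25.52
TPTOH,0.53e-6,310,-37.24
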
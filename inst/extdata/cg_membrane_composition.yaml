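# Coarse-grain bilayer composition used in the transporter simulations:
# lipid counts per system, with the nominal composition they realise.
popc: 301
chol: 74
nominal_chol_pct: 20
nominal_ratio: "4:1"
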
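# Residue presets for the human dopamine transporter (author numbering).
# tm5_ic_half   : intracellular half of TM5 (RMSD / helicity probe window)
# tm5_full      : full TM5 segment (kink-angle probe; excluded from core fits)
# core_fit_exclusions: termini, TM5 and EC loop 2 left out of core superposition
# pca_core      : C-alpha core used for principal component analysis
# na2_site      : residues coordinating the second sodium site
# ic_exit_path  : residues lining the intracellular exit pathway (SASA probe)
# t_probe       : phosphorylation-site threonine monitored by its own SASA
numbering: hdat
tm5_ic_half: "258-273"
tm5_full: "256-286"
tm5_hinge: 273
core_fit_exclusions: ["58-65", "595-601", "256-286", "178-236"]
pca_core: ["66-171", "232-548"]
na2_site: [75, 78, 418, 421, 422]
ic_exit_path: [69, 72, 75, 258, 262, 266, 269, 332, 425, 428, 432]
t_probe: 261
ec_gates:
  - {label: "R85-D476", a: 85, b: 476, type: salt_bridge}
  - {label: "Y156-F320", a: 156, b: 320, type: aromatic}
ic_gates:
  - {label: "R445-E428", a: 445, b: 428, type: salt_bridge}
  - {label: "Y335-E428", a: 335, b: 428, type: polar}
  - {label: "R60-D436", a: 60, b: 436, type: salt_bridge}
extra_pairs:
  - {label: "S262-D68", a: 262, b: 68, type: polar}
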
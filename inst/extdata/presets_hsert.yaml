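# Residue presets for the human serotonin transporter (author numbering).
# Gate pairs and the threonine SASA probe are the hSERT analogues of the
# hDAT monitors; segment ranges (TM5 window, core exclusions, PCA core,
# Na2 site, IC exit path) are carried over from the hDAT preset, which is
# how the probe suite treats the two transporters on a common footing.
# Override any key in a custom preset file for an hSERT-specific mapping.
numbering: hsert
tm5_ic_half: "258-273"
tm5_full: "256-286"
tm5_hinge: 273
core_fit_exclusions: ["58-65", "595-601", "256-286", "178-236"]
pca_core: ["66-171", "232-548"]
na2_site: [75, 78, 418, 421, 422]
ic_exit_path: [69, 72, 75, 258, 262, 266, 269, 332, 425, 428, 432]
t_probe: 276
ec_gates:
  - {label: "R104-D493", a: 104, b: 493, type: salt_bridge}
  - {label: "Y178-F335", a: 178, b: 335, type: aromatic}
ic_gates:
  - {label: "Y350-E444", a: 350, b: 444, type: polar}
  - {label: "E444-R462", a: 462, b: 444, type: salt_bridge}
  - {label: "R79-D452", a: 79, b: 452, type: salt_bridge}
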
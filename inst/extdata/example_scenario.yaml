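# Example simulation scenario: proton beam entrance and reference X-rays,
# no added scavenger. Yields in events per Mbp per Gy; doses in Gy.
plasmid:
  name: pBR322
  length_bp: 4361
  bp_nm: 0.34
replicates: 3
n_molecules: 2500
noise_cv: 0.05
doses: [0, 1, 2, 4, 8, 10]
enzyme_doses:
  fpg: [0, 1, 2, 4]
  nth: [0, 1, 2, 4]
reference: xray
conditions:
  - id: proton_entrance
    position: entrance
    let_kev_um: 1
    yields:
      ssb: 101.101
      dsb: 1.914
      base_purine: 137.926
      base_pyrimidine: 137.926
      cluster: 10.908
    scavenger:
      name: none
  - id: xray
    position: entrance
    let_kev_um: 1
    yields:
      ssb: 89.559
      dsb: 3.147
      base_purine: 95.551
      base_pyrimidine: 95.551
      cluster: 14.723
    scavenger:
      name: none
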
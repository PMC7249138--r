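# Dispersed random-coil fixture: 80 chains in a 512 nm^3 box, the study's
# system size, analysed at the four study pH values.
peptide:
  sequence: AAAAAAK
ph: [2, 7, 8, 11]
generator:
  placement: dispersed
  n_chains: 80
  box_nm: 8
  min_dist_A: 4
  motif: coil
  n_frames: 1
  seed: 42
cluster_cutoff: 4.5
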
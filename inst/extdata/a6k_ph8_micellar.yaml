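# Uncapped A6K near its isoelectric point: micellar fixture with planted
# beta-turn windows, analysed at the four study pH values.
peptide:
  sequence: AAAAAAK
  n_term: free
  c_term: free
ph: [2, 7, 8, 11]
pka_set: bjellqvist
generator:
  placement: micellar
  n_chains: 12
  box_nm: 8
  motif: beta_turn_II
  turn_position: 3
  n_frames: 2
  seed: 42
turn_criteria:
  ca_dist_max: 7.0
  hbond_ON_max: 3.5
  hbond_angle_min: 120
  combine: either
  exclude_helix: true
cluster_cutoff: 4.5
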
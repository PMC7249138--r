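# Secondary-structure classification, hydrogen bonds, beta-turn windows
# and ensemble content.

test_that("dihedrals are undefined exactly at the termini", {
  cf <- build_chain("AA", list(phi = c(NA, -139), psi = c(135, NA)))
  d <- backbone_dihedrals(cf)
  expect_true(is.na(d$phi[1]) && !is.na(d$phi[2]))
  expect_true(!is.na(d$psi[1]) && is.na(d$psi[2]))
})

test_that("classifier labels canonical motifs as expected", {
  ss_h <- classify_ss(make_motif("AAAAAAK", "alpha_helix"))
  expect_equal(ss_h[2:6], rep("helix", 5))  # interior residues

  ss_e <- classify_ss(make_motif("AAAAAAK", "extended"))
  expect_true(all(ss_e[2:6] == "sheet"))
  expect_false(any(ss_e == "turn"))

  ss_t <- classify_ss(make_motif("AAAAAAK", "beta_turn_II",
                                 turn_position = 3))
  expect_equal(ss_t[4:5], c("turn", "turn"))  # inner window residues
})

test_that("helical backbones form the i to i+4 hydrogen-bond ladder", {
  h <- make_motif("AAAAAAK", "alpha_helix")
  hb <- find_hbonds(h)
  ladder <- hb[hb$donor - hb$acceptor == 4, ]
  expect_equal(nrow(ladder), 3L)  # donors 5, 6, 7
  expect_true(all(ladder$dist_ON >= 2.8 & ladder$dist_ON <= 3.2))

  # chains far apart share no hydrogen bonds across residues
  far <- build_chain("AA", list(phi = c(NA, -139), psi = c(135, NA)))
  expect_equal(nrow(find_hbonds(far)), 0L)
})

test_that("proline cannot donate a backbone hydrogen bond", {
  h <- make_motif("AAAAPAK", "alpha_helix")
  hb <- find_hbonds(h)
  expect_false(any(hb$donor == 5))
  expect_true(any(hb$donor == 6))
})

test_that("planted turn fixtures yield exactly one record", {
  for (m in c("beta_turn_I", "beta_turn_II")) {
    cf <- make_motif("AAAAAAK", m, turn_position = 3)
    rec <- detect_beta_turns(cf)
    expect_equal(rec$start, 3L)
    expect_equal(rec$start, oracle_beta_turn_starts(cf))
  }
  # helices satisfy the distance criterion but are excluded
  h <- make_motif("AAAAAAK", "alpha_helix")
  expect_equal(nrow(detect_beta_turns(h)), 0L)
  expect_gt(length(oracle_beta_turn_starts(h)), 0L)  # geometry alone fires
  # extended chains satisfy neither criterion
  expect_equal(nrow(detect_beta_turns(make_motif("AAAAAAK", "extended"))),
               0L)
  # chains shorter than one window yield nothing
  short <- build_chain("AAA", list(phi = rep(-60, 3), psi = rep(-30, 3)))
  expect_equal(nrow(detect_beta_turns(short)), 0L)
})

test_that("window detection agrees with the brute-force oracle", {
  set.seed(2024)
  crit <- turn_criteria(exclude_helix = FALSE)
  for (rep in 1:100) {
    cf <- random_chain(sample(5:9, 1))
    got <- detect_beta_turns(cf, crit)$start
    expect_identical(as.integer(got),
                     as.integer(oracle_beta_turn_starts(cf)))
  }
})

test_that("the C-alpha criterion is strict at the threshold", {
  cf <- make_motif("AAAAAAK", "beta_turn_II", turn_position = 3)
  d <- o_norm(o_xyz(cf, 3, "CA") - o_xyz(cf, 6, "CA"))
  # disable the hydrogen-bond route so only criterion B can fire
  at_thr <- turn_criteria(ca_dist_max = d, hbond_ON_max = 1e-6)
  above <- turn_criteria(ca_dist_max = d + 1e-9, hbond_ON_max = 1e-6)
  expect_equal(nrow(detect_beta_turns(cf, at_thr)), 0L)   # strict <
  expect_equal(detect_beta_turns(cf, above)$start, 3L)
})

test_that("record counts are monotone in the distance cutoff", {
  set.seed(31)
  for (rep in 1:10) {
    cf <- random_chain(9)
    counts <- sapply(c(4, 5.5, 7, 8.5, 10, 12), function(mx)
      nrow(detect_beta_turns(cf, turn_criteria(ca_dist_max = mx,
                                               exclude_helix = FALSE))))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("ensemble content recovers planted window fractions exactly", {
  sys <- make_system("AAAAAAK", n_chains = 10, seed = 42, n_frames = 5,
                     per_chain_motif = "beta_turn_II", turn_position = 3)
  tc <- turn_content(sys)
  # one window of four residues per 7-residue chain
  expect_equal(tc$per_frame$beta_turn_percent, rep(100 * 4 / 7, 5))
  expect_equal(tc$sd[["beta_turn"]], 0)

  # window-denominator mode: 1 qualifying window out of 4
  tw <- turn_content(sys, denominator = "windows")
  expect_equal(tw$beta_turn_percent, 25)

  helices <- make_system("AAAAAAK", n_chains = 6, seed = 1,
                         per_chain_motif = "alpha_helix")
  expect_equal(turn_content(helices)$beta_turn_percent, 0)

  half <- make_system("AAAAAAK", n_chains = 10, seed = 7,
                      per_chain_motif = c("beta_turn_II", "extended"),
                      turn_position = 3)
  expect_equal(turn_content(half)$beta_turn_percent,
               tc$beta_turn_percent / 2)
})

test_that("content percentages are bounded and chain-order invariant", {
  sys <- make_system("AAAAAAK", n_chains = 8, seed = 13, n_frames = 3)
  tc <- turn_content(sys)
  expect_true(all(tc$per_frame$turn_percent >= 0 &
                  tc$per_frame$turn_percent <= 100))
  expect_true(all(tc$per_frame$beta_turn_percent >= 0 &
                  tc$per_frame$beta_turn_percent <= 100))
  shuffled <- sys
  shuffled$frames <- lapply(shuffled$frames, function(fr) rev(fr))
  tc2 <- turn_content(shuffled)
  expect_equal(tc2$per_frame, tc$per_frame)

  expect_error(turn_content(peptide_system(list(list()))), "empty")
})
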
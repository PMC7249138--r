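# Contact clustering, geometry reports and electrostatic scores.

test_that("contact clustering follows the single-linkage definition", {
  A <- point_chain(c(0, 0, 0), "A")
  B <- point_chain(c(0, 4, 0), "B")
  C <- point_chain(c(0, 8, 0), "C")
  near <- contact_clusters(list(A, point_chain(c(0, 3, 0), "B")), 4.5)
  expect_equal(length(near$sizes), 1L)
  far <- contact_clusters(list(A, point_chain(c(0, 50, 0), "B")), 4.5)
  expect_equal(length(far$sizes), 2L)
  # A-B and B-C in contact, A-C 8 apart: one cluster by transitivity
  tri <- contact_clusters(list(A, B, C), 4.5)
  expect_equal(length(tri$sizes), 1L)
  expect_equal(tri$sizes, 3L)
  expect_error(contact_clusters(list(), 4.5), "empty")
})

test_that("cluster labels match a brute-force component oracle", {
  for (seed in c(3, 17)) {
    sys <- make_system("AAAAAAK", n_chains = 12, box_nm = 6, seed = seed)
    fr <- sys$frames[[1]]
    for (cutoff in c(4.5, 8, 15)) {
      got <- contact_clusters(fr, cutoff)
      want <- oracle_components(fr, cutoff)
      # same partition: equal label co-membership matrices
      expect_identical(outer(got$membership, got$membership, "=="),
                       outer(want, want, "=="))
      expect_equal(sum(got$sizes), 12L)
    }
  }
})

test_that("radius of gyration has its closed forms and invariances", {
  one <- data.frame(res = 1, letter = "A", atom = "CA", elem = "C",
                    x = 1, y = 2, z = 3)
  expect_equal(radius_of_gyration(one), 0)
  two <- data.frame(res = c(1, 1), letter = "A", atom = c("CA", "CB"),
                    elem = "C", x = c(0, 2), y = 0, z = 0)
  expect_equal(radius_of_gyration(two), 1.0)
  cf <- make_motif("AAAAAAK", "alpha_helix")
  rg <- radius_of_gyration(cf)
  moved <- rotate_conf(cf, rot_z(73), shift = c(5, -2, 11))
  expect_equal(radius_of_gyration(moved), rg, tolerance = 1e-9)
})

test_that("micellar aggregates have positive amphiphilic order", {
  sys <- make_system("AAAAAAK", n_chains = 12, placement = "micellar",
                     per_chain_motif = "extended", seed = 21)
  ap <- amphiphilic_profile(sys$frames[[1]])
  expect_gt(ap$amphiphilic_order, 0)
  # rigid rotation + translation leaves the report unchanged
  moved <- lapply(sys$frames[[1]], rotate_conf, R = rot_z(40),
                  shift = c(3, 4, 5))
  ap2 <- amphiphilic_profile(moved)
  expect_equal(ap2$amphiphilic_order, ap$amphiphilic_order,
               tolerance = 1e-6)
  expect_equal(ap2$mean_radial_ala_cb, ap$mean_radial_ala_cb,
               tolerance = 1e-6)
  expect_error(amphiphilic_profile(sys$frames[[1]][1:2]), "at least 3")
})

test_that("dispersed placement shows no radial amphiphilic ordering", {
  orders <- sapply(1:20, function(s) {
    sys <- make_system("AAAAAAK", n_chains = 10, box_nm = 8,
                       placement = "dispersed", seed = 1000 + s)
    amphiphilic_profile(sys$frames[[1]])$amphiphilic_order
  })
  # symmetric about zero: the 20-seed mean is statistically compatible
  # with no ordering
  expect_gt(stats::t.test(orders)$p.value, 0.01)
  expect_lt(abs(mean(orders)), 2)
})

test_that("electrostatic scores are repulsive at pH 2, symmetric, cut off", {
  base <- make_motif("AAAAAAK", "extended")
  other <- rotate_conf(base, rot_z(35), shift = c(6, 3, 2))
  s_ab <- pair_electrostatic_score(base, other, pH = 2)
  expect_gt(s_ab, 0)  # all sites positive at pH 2: pure repulsion
  expect_equal(pair_electrostatic_score(other, base, pH = 2), s_ab)
  # beyond the 1.4 nm cutoff the score vanishes exactly
  distant <- rotate_conf(base, diag(3), shift = c(60, 0, 0))
  expect_equal(pair_electrostatic_score(base, distant, pH = 2), 0)
})

test_that("scores decay toward zero along a separation series", {
  base <- make_motif("AAAAAAK", "extended")
  seps <- c(6, 8, 10, 12)
  s2 <- sapply(seps, function(d)
    pair_electrostatic_score(base, rotate_conf(base, diag(3),
                                               shift = c(0, 0, d)),
                             pH = 2))
  expect_true(all(diff(abs(s2)) < 0))  # pure repulsion decays monotonically
  # near the isoelectric pH two neutral-net chains interact weakly
  pI <- isoelectric_point("AAAAAAK", digits = NULL)
  s_pI <- pair_electrostatic_score(base, rotate_conf(base, diag(3),
                                                     shift = c(0, 0, 13)),
                                   pH = pI)
  expect_lt(abs(s_pI), abs(pair_electrostatic_score(
    base, rotate_conf(base, diag(3), shift = c(0, 0, 13)), pH = 2)))
})

test_that("the frame report combines sizes, gyration and scores", {
  sys <- make_system("AAAAAAK", n_chains = 6, box_nm = 6, seed = 9)
  rep <- aggregate_report(sys$frames[[1]], cutoff_A = 4.5, pH = 8)
  expect_equal(sum(rep$aggregates$size), 6L)
  expect_true(all(rep$aggregates$rgyr_A >= 0))
  expect_true(isSymmetric(rep$electrostatic))
  expect_output(print(rep), "aggregate")
})
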
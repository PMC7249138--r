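# Internal-coordinate builder, motif templates, coil sampling, packing.

test_that("trans extended chains have canonical C-alpha spacing", {
  cf <- make_motif("AAAAAAK", "extended")
  ca <- t(sapply(1:7, function(i) o_xyz(cf, i, "CA")))
  d <- sqrt(rowSums((ca[-1, ] - ca[-7, ])^2))
  expect_true(all(abs(d - 3.80) <= 0.02))
})

test_that("build/measure dihedral round trip holds for random chains", {
  set.seed(101)
  worst <- 0
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    seq <- paste(sample(c("A", "K", "S", "V"), n, TRUE), collapse = "")
    phi <- runif(n, -179.9, 179.9)
    psi <- runif(n, -179.9, 179.9)
    om <- runif(n, -179.9, 179.9)
    cf <- build_chain(seq, list(phi = phi, psi = psi, omega = om))
    d <- backbone_dihedrals(cf)
    worst <- max(worst,
                 abs(d$phi[-1] - phi[-1]),
                 abs(d$psi[-n] - psi[-n]),
                 abs(d$omega[-n] - om[-n]))
  }
  expect_lt(worst, 1e-6)
})

test_that("generated residues are L (negative N-CA-C-CB improper)", {
  set.seed(7)
  for (rep in 1:5) {
    cf <- random_chain(8)
    for (i in 1:8) {
      cb <- o_xyz(cf, i, "CB")
      if (is.null(cb)) next  # Gly
      imp <- dihedral_angle(o_xyz(cf, i, "N"), o_xyz(cf, i, "CA"),
                            o_xyz(cf, i, "C"), cb)
      expect_lt(imp, 0)
      expect_equal(abs(imp), 121.3, tolerance = 2)
    }
  }
})

test_that("single residues and mismatched dihedral lists are rejected", {
  expect_error(build_chain("A", list(phi = 0, psi = 0)), "at least 2")
  expect_error(build_chain("AAA", list(phi = c(0, 0), psi = c(0, 0))),
               "match the sequence length")
})

test_that("motif templates plant the intended geometry", {
  h <- make_motif("AAAAAAK", "alpha_helix")
  d <- backbone_dihedrals(h)
  expect_equal(d$phi[2:7], rep(-57, 6), tolerance = 1e-9)
  expect_equal(d$psi[1:6], rep(-47, 6), tolerance = 1e-9)

  t2 <- make_motif("AAAAAAK", "beta_turn_II", turn_position = 3)
  ca3 <- o_xyz(t2, 3, "CA"); ca6 <- o_xyz(t2, 6, "CA")
  expect_lt(o_norm(ca3 - ca6), 7)

  ext <- make_motif("AAAAAAK", "extended")
  for (i in 1:4)
    expect_gt(o_norm(o_xyz(ext, i, "CA") - o_xyz(ext, i + 3, "CA")), 7)

  expect_error(make_motif("AAAAAAK", "pi_helix"), "unknown motif")
  expect_error(make_motif("AAAA", "beta_turn_I", turn_position = 2),
               "window")
})

test_that("coil sampling is seed-deterministic and basin-faithful", {
  a <- sample_coil("AAAAAAK", seed = 42)
  b <- sample_coil("AAAAAAK", seed = 42)
  expect_identical(a$atoms, b$atoms)
  c <- sample_coil("AAAAAAK", seed = 43)
  expect_false(identical(a$atoms, c$atoms))

  # all-beta weights put every residue in the beta basin
  onlyb <- sample_coil("AAAAAAKAAA", seed = 1,
                       basin_weights = c(beta = 1, alphaR = 0, alphaL = 0))
  d <- backbone_dihedrals(onlyb)
  inner <- 2:9
  expect_true(all(d$phi[inner] >= -180 & d$phi[inner] <= -60))
  expect_true(all(d$psi[inner] >= 60 & d$psi[inner] <= 180))

  expect_error(sample_coil("AAA", seed = 1,
                           basin_weights = c(beta = 0.6, alphaR = 0.6,
                                             alphaL = 0.1)),
               "sum to 1")
})

test_that("coil basin occupancy matches the multinomial expectation", {
  n <- 1000
  long <- paste(rep("A", n), collapse = "")
  w <- c(beta = 0.5, alphaR = 0.4, alphaL = 0.1)
  cf <- sample_coil(long, seed = 99, basin_weights = w)
  counts <- table(factor(attr(cf, "basins"), levels = names(w)))
  for (b in names(w)) {
    expe <- n * w[[b]]
    sd3 <- 3 * sqrt(n * w[[b]] * (1 - w[[b]]))
    expect_lt(abs(counts[[b]] - expe), sd3)
  }
})

test_that("dispersed packing enforces the minimum inter-chain distance", {
  sys <- make_system("AAAAAAK", n_chains = 80, box_nm = 8,
                     placement = "dispersed", min_dist_A = 4, seed = 42)
  fr <- sys$frames[[1]]
  expect_length(fr, 80L)
  heavy <- lapply(fr, function(cf)
    as.matrix(cf$atoms[cf$atoms$elem != "H", c("x", "y", "z")]))
  dmin <- Inf
  for (i in 1:79) for (j in (i + 1):80) {
    d2 <- outer(rowSums(heavy[[i]]^2), rowSums(heavy[[j]]^2), "+") -
      2 * heavy[[i]] %*% t(heavy[[j]])
    dmin <- min(dmin, sqrt(max(0, min(d2))))
  }
  expect_gte(dmin, 4)
})

test_that("micellar systems point lysine outward and packing can fail", {
  sys <- make_system("AAAAAAK", n_chains = 12, placement = "micellar",
                     per_chain_motif = "extended", seed = 5)
  fr <- sys$frames[[1]]
  centre <- c(40, 40, 40)  # box centre; generator axis is z
  rad <- function(p) o_norm((p - centre)[1:2])
  r_nz <- mean(sapply(fr, function(cf) rad(o_xyz(cf, 7, "NZ"))))
  r_cb <- mean(sapply(fr, function(cf)
    mean(sapply(1:6, function(i) rad(o_xyz(cf, i, "CB"))))))
  expect_gt(r_nz, r_cb)

  single <- make_system("AAAAAAK", n_chains = 1, seed = 2)
  expect_length(single$frames[[1]], 1L)

  expect_error(
    make_system("AAAAAAK", n_chains = 30, box_nm = 1.2, seed = 3,
                min_dist_A = 6, max_attempts = 25),
    "packing failed")
})

test_that("system generation is a pure function of its seed", {
  a <- make_system("AAAAAAK", n_chains = 6, seed = 8, n_frames = 2,
                   per_chain_motif = c("coil", "beta_turn_II"))
  b <- make_system("AAAAAAK", n_chains = 6, seed = 8, n_frames = 2,
                   per_chain_motif = c("coil", "beta_turn_II"))
  expect_identical(a, b)
})
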
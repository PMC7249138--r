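# Henderson-Hasselbalch charge model, pI, mass and charge-state labels.

a6k <- peptide("AAAAAAK")

test_that("ionizable site enumeration respects termini blocking", {
  s <- ionizable_sites(a6k)
  expect_equal(s$site_kind, c("n_terminus", "side_chain", "c_terminus"))
  expect_equal(s$pKa, c(7.59, 10.00, 3.55))
  expect_equal(s$polarity, c("base", "base", "acid"))
  expect_equal(s$residue_index, c(1L, 7L, 7L))

  capped <- peptide("AAAAAAK", n_term = "blocked", c_term = "blocked")
  expect_equal(nrow(ionizable_sites(capped)), 1L)
  expect_equal(ionizable_sites(capped)$site_kind, "side_chain")

  expect_equal(nrow(ionizable_sites(peptide("AAAA"))), 2L)
  expect_error(peptide("AAXK"), "position 3")
})

test_that("fractional charges follow the closed form", {
  expect_equal(fractional_charge(10, "base", 10), 0.5)
  expect_equal(fractional_charge(3.55, "acid", 3.55), -0.5)
  # independent closed-form evaluation
  expect_equal(fractional_charge(3.55, "acid", 2),
               -1 / (1 + 10^(3.55 - 2)), tolerance = 1e-12)
  expect_equal(round(fractional_charge(3.55, "acid", 2), 4), -0.0274)
  # strictly decreasing in pH for both polarities
  grid <- seq(0, 14, by = 0.05)
  expect_true(all(diff(fractional_charge(10, "base", grid)) < 0))
  expect_true(all(diff(fractional_charge(4, "acid", grid)) < 0))
  expect_error(fractional_charge(10, "base", -0.5), "pH")
})

test_that("A6K net charge reproduces the printed charge states", {
  # independent oracle: explicit three-site sum
  oracle <- function(h)
    1 / (1 + 10^(h - 7.59)) + 1 / (1 + 10^(h - 10)) - 1 / (1 + 10^(3.55 - h))
  nc <- net_charge(a6k, c(2, 7, 8, 11))
  expect_equal(nc$net_charge, sapply(c(2, 7, 8, 11), oracle),
               tolerance = 1e-12)
  expect_equal(nc$net_charge[1], 1.9726, tolerance = 1e-4)
  expect_equal(nc$net_charge[4], -0.9087, tolerance = 1e-4)
  expect_equal(nc$rounded, c(2L, 1L, 0L, -1L))
})

test_that("net charge is strictly decreasing and bounded by site counts", {
  grid <- seq(0, 14, by = 0.05)
  for (seqs in list(c("AAAAAAK", "free", "free"),
                    c("DEKRH", "free", "free"),
                    c("AAAAAAK", "blocked", "free"))) {
    p <- peptide(seqs[1], n_term = seqs[2], c_term = seqs[3])
    s <- ionizable_sites(p)
    q <- net_charge(p, grid)$net_charge
    expect_true(all(diff(q) < 0))
    expect_true(all(q >= -sum(s$polarity == "acid") - 1e-12))
    expect_true(all(q <= sum(s$polarity == "base") + 1e-12))
  }
})

test_that("bisection pI matches a brute-force scan and the two-site mean", {
  for (s in c("AAAAAAK", "DK", "AEKR")) {
    root <- isoelectric_point(s, digits = NULL)
    m <- protonation_model(s)
    expect_lt(abs(predict(m, root)), 1e-4)
    grid <- seq(0, 14, by = 1e-4)
    scan <- grid[which.min(abs(predict(m, grid)))]
    expect_lt(abs(root - scan), 1e-3)
  }
  # a single free residue is a two-site zwitterion: pI is the pKa mean
  expect_equal(isoelectric_point("A", digits = 2), (3.55 + 7.59) / 2,
               tolerance = 0.01)
  # pI invariant under appending non-ionizable residues
  expect_equal(isoelectric_point("AAK", digits = NULL),
               isoelectric_point("AAKAA", digits = NULL), tolerance = 1e-6)
  expect_error(
    isoelectric_point(peptide("AAAAAAK", n_term = "blocked",
                              c_term = "blocked")),
    "no isoelectric point")
})

test_that("molecular mass is additive over residues plus terminal water", {
  expect_equal(round(molecular_weight(a6k), 2), 572.66)
  expect_equal(round(molecular_weight("G"), 2), 75.07)
  # independent per-residue summation (masses restated, not read from
  # package internals)
  expect_equal(molecular_weight("GASV"),
               57.0519 + 71.0788 + 87.0782 + 99.1326 + 18.0153,
               tolerance = 1e-6)
  for (s in c("AAAAAAK", "WYR", "GG"))
    expect_lte(molecular_weight(s, "monoisotopic"), molecular_weight(s))
  expect_error(peptide(""), "non-empty")
})

test_that("charge-state labels reproduce the qualitative narrative", {
  st8 <- charge_state(a6k, 8)
  expect_equal(st8$sites$label,
               c("mostly_neutral", "charged", "charged"))
  expect_equal(st8$rounded_net_charge, 0L)
  st2 <- charge_state(a6k, 2)
  expect_equal(st2$sites$label[st2$sites$site_kind == "c_terminus"],
               "neutral")
  expect_equal(st2$rounded_net_charge, 2L)
  # a site at its own pKa is half-charged, hence mixed
  stk <- charge_state(a6k, 10)
  expect_equal(stk$sites$label[stk$sites$site_kind == "side_chain"],
               "mixed")
})

test_that("titration curves preserve grid order and monotonicity", {
  expect_equal(nrow(titration_curve(a6k, numeric(0))), 0L)
  grid <- c(11, 2, 8, 7)
  tc <- titration_curve(a6k, grid)
  expect_equal(tc$pH, grid)
  expect_equal(tc$rounded, c(-1L, 2L, 0L, 1L))
  inc <- titration_curve(a6k, seq(1, 13, by = 0.25))
  expect_true(all(diff(inc$net_charge) < 0))
})

test_that("pKa overrides from file change the model", {
  f <- tempfile()
  writeLines(c("c_term 4.0", "K 10.5", "n_term:A 8.0"), f)
  set <- read_pka_set(f)
  s <- ionizable_sites(a6k, set)
  expect_equal(s$pKa, c(8.0, 10.5, 4.0))
  writeLines("Z 5.0", f)
  expect_error(read_pka_set(f), "unknown pKa site key")
})
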
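# Internal-coordinate backbone construction: sequential (NeRF-style)
# placement of N, CA, C from bond lengths, bond angles and the (phi, psi,
# omega) torsions, followed by O, amide H, CB and the Lys NZ pseudo-atom.
#
# Dihedral bookkeeping for residue i (1-based):
#   phi[i]   = C(i-1)-N(i)-CA(i)-C(i)      (NA for i = 1)
#   psi[i]   = N(i)-CA(i)-C(i)-N(i+1)      (NA for i = n)
#   omega[i] = CA(i)-C(i)-N(i+1)-CA(i+1)   (NA for i = n)

#' Backbone geometry parameters
#'
#' Standard bond lengths (Angstrom) and bond angles (degrees) for the
#' trans peptide backbone. Override individual entries via `...`.
#'
#' @param ... Named overrides, e.g. `b_ca_c = 1.52`.
#' @return Named list of class `geometry_params`.
#' @export
geometry_params <- function(...) {
  g <- list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    b_n_h = 1.01, b_ca_cb = 1.521, b_ca_nz = 4.9,
    a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
    a_ca_c_o = 120.8, a_n_ca_cb = 110.4,
    # torsion C-N-CA-CB fixing L-chirality (measured on the ideal
    # L-alanine template; D would be +120)
    t_cb = -120,
    omega_trans = 180)
  over <- list(...)
  stopifnot(all(names(over) %in% names(g)))
  g[names(over)] <- over
  structure(g, class = "geometry_params")
}

#' Canonical dihedral motif templates
#'
#' Named (phi, psi) templates: `alpha_helix` (-57, -47), `extended`
#' (-139, 135), `ppII` (-75, 145), and the ideal four-residue beta-turn
#' types `beta_turn_I` (i+1: -60, -30; i+2: -90, 0) and `beta_turn_II`
#' (i+1: -60, 120; i+2: 80, 0).
#'
#' @return Named list; repetitive motifs hold a single (phi, psi) pair,
#'   turn motifs hold the two inner-residue pairs.
#' @export
motif_library <- function() {
  list(
    alpha_helix = list(kind = "repeat", phi = -57, psi = -47),
    extended = list(kind = "repeat", phi = -139, psi = 135),
    ppII = list(kind = "repeat", phi = -75, psi = 145),
    beta_turn_I = list(kind = "turn",
                       phi = c(-60, -90), psi = c(-30, 0)),
    beta_turn_II = list(kind = "turn",
                        phi = c(-60, 80), psi = c(120, 0)))
}

#' @keywords internal
as_dihedral_set <- function(d, n) {
  if (is.data.frame(d)) d <- as.list(d)
  stopifnot(all(c("phi", "psi") %in% names(d)))
  if (is.null(d$omega)) d$omega <- rep(180, n)
  if (length(d$phi) != n || length(d$psi) != n || length(d$omega) != n)
    stop("dihedral vectors must match the sequence length", call. = FALSE)
  data.frame(phi = d$phi, psi = d$psi, omega = d$omega)
}

#' Build a peptide chain from backbone dihedrals
#'
#' Sequential internal-to-Cartesian construction. Places backbone N, CA,
#' C plus carbonyl O, amide H (from residue 2 on, in the C(prev)-N-CA
#' plane bisecting the two bonds), CB for non-Gly residues (L
#' configuration) and, for Lys, a pseudo-atom NZ on the CA->CB direction
#' at 4.9 Angstrom from CA (a charge/radial marker standing in for the
#' full side chain). A free C-terminus receives OXT. The construction is
#' the exact inverse of [backbone_dihedrals()]: measured torsions equal
#' the inputs to well below 1e-6 degrees.
#'
#' @param x A [peptide()] or sequence string (length >= 2).
#' @param dihedrals List or data.frame with `phi`, `psi` and optionally
#'   `omega` (default all-trans 180), one entry per residue; `phi[1]`,
#'   `psi[n]`, `omega[n]` are ignored (undefined at the termini).
#' @param geom A [geometry_params()].
#' @param chain_id Chain label.
#' @return A [conformation()].
#' @examples
#' d <- list(phi = rep(-57, 7), psi = rep(-47, 7))
#' helix <- build_chain("AAAAAAK", d)
#' @export
build_chain <- function(x, dihedrals, geom = geometry_params(),
                        chain_id = "A") {
  p <- as_peptide(x)
  n <- length(p$residues)
  if (n < 2L)
    stop("chain building needs at least 2 residues (no dihedrals definable)",
         call. = FALSE)
  d <- as_dihedral_set(dihedrals, n)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  # residue 1 in a canonical frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(geom$b_n_ca, 0, 0)
  ang <- geom$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + geom$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         geom$b_c_n, geom$a_ca_c_n, d$psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          geom$b_n_ca, geom$a_c_n_ca, d$omega[i - 1])
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         geom$b_ca_c, geom$a_n_ca_c, d$phi[i])
  }
  rows <- list()
  add <- function(res, letter, atom, xyz)
    rows[[length(rows) + 1L]] <<- data.frame(
      res = res, letter = letter, atom = atom, elem = element_of(atom),
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- p$residues[i]
    add(i, r, "N", N[i, ])
    if (i > 1L) {
      # amide H: in the C(i-1)-N-CA plane, opposite the bisector
      hdir <- -(unit(C[i - 1, ] - N[i, ]) + unit(CA[i, ] - N[i, ]))
      add(i, r, "H", N[i, ] + geom$b_n_h * unit(hdir))
    }
    add(i, r, "CA", CA[i, ])
    if (r != "G") {
      CB <- place_atom(C[i, ], N[i, ], CA[i, ],
                       geom$b_ca_cb, geom$a_n_ca_cb, geom$t_cb)
      add(i, r, "CB", CB)
      if (r == "K")
        add(i, r, "NZ", CA[i, ] + geom$b_ca_nz * unit(CB - CA[i, ]))
    }
    add(i, r, "C", C[i, ])
    # carbonyl O anti to the next N (psi + 180); pseudo-psi 180 at the end
    psi_i <- if (i < n) d$psi[i] else 180
    add(i, r, "O", place_atom(N[i, ], CA[i, ], C[i, ],
                              geom$b_c_o, geom$a_ca_c_o, psi_i + 180))
    if (i == n && p$c_term_free)
      add(i, r, "OXT", place_atom(N[i, ], CA[i, ], C[i, ],
                                  1.25, 117, psi_i))
  }
  conformation(do.call(rbind, rows), peptide = p, chain_id = chain_id)
}

#' Build an ideal secondary-structure motif
#'
#' Sets backbone dihedrals from a named template of [motif_library()].
#' For the turn motifs, residues `turn_position + 1` and
#' `turn_position + 2` take the template values and all flanking
#' residues are extended, so exactly one i..i+3 window is planted.
#' Deterministic.
#'
#' @inheritParams build_chain
#' @param motif Template name (see [motif_library()]).
#' @param turn_position Window start i (1-based) for turn motifs; the
#'   window i..i+3 must fit the sequence.
#' @return A [conformation()].
#' @examples
#' turn <- make_motif("AAAAAAK", "beta_turn_II", turn_position = 3)
#' @export
make_motif <- function(x, motif, turn_position = 2L,
                       geom = geometry_params(), chain_id = "A") {
  p <- as_peptide(x)
  n <- length(p$residues)
  lib <- motif_library()
  if (!motif %in% names(lib))
    stop(sprintf("unknown motif '%s'", motif), call. = FALSE)
  tpl <- lib[[motif]]
  if (tpl$kind == "repeat") {
    d <- list(phi = rep(tpl$phi, n), psi = rep(tpl$psi, n))
  } else {
    if (turn_position < 1L || turn_position + 3L > n)
      stop("turn window does not fit the sequence", call. = FALSE)
    ext <- lib$extended
    phi <- rep(ext$phi, n); psi <- rep(ext$psi, n)
    phi[turn_position + 1:2] <- tpl$phi
    psi[turn_position + 1:2] <- tpl$psi
    d <- list(phi = phi, psi = psi)
  }
  build_chain(p, d, geom = geom, chain_id = chain_id)
}

#' @keywords internal
.coil_basins <- list(
  beta = list(phi = c(-180, -60), psi = c(60, 180)),
  alphaR = list(phi = c(-90, -40), psi = c(-60, -10)),
  alphaL = list(phi = c(40, 90), psi = c(10, 60)))

#' Sample a random-coil conformation
#'
#' Per residue, a Ramachandran basin is chosen with the given weights and
#' (phi, psi) drawn uniformly within it. Basins: `beta` (phi in
#' \[-180,-60\], psi in \[60,180\]), `alphaR` (\[-90,-40\], \[-60,-10\]),
#' `alphaL` (\[40,90\], \[10,60\]). Reproducible given `seed`.
#'
#' @inheritParams build_chain
#' @param seed Integer seed (mandatory for reproducibility).
#' @param basin_weights Named weights over `beta`, `alphaR`, `alphaL`;
#'   must sum to 1 within 1e-9.
#' @return A [conformation()]; the sampled basins are attached as
#'   attribute `"basins"`.
#' @export
sample_coil <- function(x, seed,
                        basin_weights = c(beta = 0.5, alphaR = 0.4,
                                          alphaL = 0.1),
                        geom = geometry_params(), chain_id = "A") {
  p <- as_peptide(x)
  n <- length(p$residues)
  w <- basin_weights[names(.coil_basins)]
  if (any(is.na(w)) || abs(sum(w) - 1) > 1e-9)
    stop("basin_weights must cover beta/alphaR/alphaL and sum to 1",
         call. = FALSE)
  with_seed(seed, {
    basins <- sample(names(.coil_basins), n, replace = TRUE, prob = w)
    phi <- psi <- numeric(n)
    for (i in seq_len(n)) {
      b <- .coil_basins[[basins[i]]]
      phi[i] <- stats::runif(1, b$phi[1], b$phi[2])
      psi[i] <- stats::runif(1, b$psi[1], b$psi[2])
    }
    cf <- build_chain(p, list(phi = phi, psi = psi), geom = geom,
                      chain_id = chain_id)
    attr(cf, "basins") <- basins
    cf
  })
}
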
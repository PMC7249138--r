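# Coarse secondary-structure assignment from backbone dihedrals, backbone
# hydrogen-bond detection, and the two classic beta-turn criteria over
# i..i+3 windows:
#   A: a hydrogen bond between the C=O of residue i and the N-H of i+3
#   B: a C-alpha(i) to C-alpha(i+3) distance below 7 Angstrom
# Ensemble turn/beta-turn percentages are averaged over frames.

#' Beta-turn and hydrogen-bond detection thresholds
#'
#' @param ca_dist_max Maximum C-alpha(i)-C-alpha(i+3) distance in
#'   Angstrom (strict `<`; default 7.0).
#' @param hbond_ON_max Maximum O...N distance for a backbone hydrogen
#'   bond (Angstrom, default 3.5).
#' @param hbond_angle_min Minimum N-H...O angle at the hydrogen
#'   (degrees, default 120).
#' @param combine `"either"` (default): a window qualifies on either
#'   criterion; `"both"`: both required.
#' @param exclude_helix Reject windows whose inner residues (i+1, i+2)
#'   are helix-labelled (default `TRUE`: beta-turns classically require
#'   non-helical residues).
#' @return Named list of class `turn_criteria`.
#' @export
turn_criteria <- function(ca_dist_max = 7.0, hbond_ON_max = 3.5,
                          hbond_angle_min = 120,
                          combine = c("either", "both"),
                          exclude_helix = TRUE) {
  combine <- match.arg(combine)
  stopifnot(ca_dist_max > 0, hbond_ON_max > 0, hbond_angle_min > 0)
  structure(list(ca_dist_max = ca_dist_max, hbond_ON_max = hbond_ON_max,
                 hbond_angle_min = hbond_angle_min, combine = combine,
                 exclude_helix = exclude_helix),
            class = "turn_criteria")
}

#' Measure backbone dihedrals of a conformation
#'
#' Standard phi (C'(i-1)-N-CA-C'), psi (N-CA-C'-N(i+1)) and omega
#' (CA-C'-N(i+1)-CA(i+1)), in degrees, NA where undefined (chain termini)
#' or where a residue lacks backbone atoms.
#'
#' @param conf A [conformation()].
#' @return Data.frame with columns `phi`, `psi`, `omega`, one row per
#'   residue.
#' @export
backbone_dihedrals <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  n <- length(conf$peptide$residues)
  N <- atom_matrix(conf, "N"); CA <- atom_matrix(conf, "CA")
  C <- atom_matrix(conf, "C")
  if (any(!conf$usable))
    warning(sprintf("%d residue(s) unusable; dihedrals set to NA",
                    sum(!conf$usable)), call. = FALSE)
  ok <- conf$usable & stats::complete.cases(N) & stats::complete.cases(CA) &
    stats::complete.cases(C)
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    if (i > 1L && ok[i - 1])
      phi[i] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < n && ok[i + 1]) {
      psi[i] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
      omega[i] <- dihedral_angle(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ])
    }
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}

# Dihedral-region membership. The sheet (beta) region is half-open in
# phi ([-180, -60)) so canonical turn templates sitting exactly on the
# -60 boundary are not absorbed into sheet runs. Angles are rounded to
# 1e-6 degrees first: rigid-body motion perturbs measured dihedrals at
# the 1e-12 level, which must not flip a boundary classification.
#' @keywords internal
.r6 <- function(x) round(x, 6)

#' @keywords internal
.in_alphaR <- function(phi, psi) {
  phi <- .r6(phi); psi <- .r6(psi)
  !is.na(phi) & !is.na(psi) & phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
}

#' @keywords internal
.in_beta <- function(phi, psi) {
  phi <- .r6(phi); psi <- .r6(psi)
  !is.na(phi) & !is.na(psi) & phi >= -180 & phi < -60 &
    ((psi >= 60 & psi <= 180) | (psi > -180 & psi <= -150))
}

#' @keywords internal
.runs_at_least <- function(flag, k) {
  r <- rle(flag)
  keep <- r$values & r$lengths >= k
  rep(keep, r$lengths)
}

#' Classify coarse secondary structure
#'
#' Per-residue labels in `helix`, `sheet`, `turn`, `coil`, assigned from
#' backbone dihedral regions plus a C-alpha window test: helix for runs
#' of >= 4 consecutive residues in the alpha-R region (phi in
#' \[-100,-30\], psi in \[-80,-5\]); sheet for runs of >= 2 in the beta
#' region (phi in \[-180,-60), psi in \[60,180\] or (-180,-150\]); then
#' residues inside any i..i+3 window with C-alpha(i)-C-alpha(i+3) <
#' `ca_dist_max` that are not helix or sheet become turn; the rest is
#' coil. Residues lacking dihedrals (termini) can still join a turn
#' window, otherwise default to coil. This is a documented stand-in for
#' hydrogen-bond-energetics assigners such as STRIDE, not a
#' re-implementation.
#'
#' @param conf A [conformation()].
#' @param dihedrals Optional precomputed [backbone_dihedrals()] output.
#' @param ca_dist_max Turn-window C-alpha distance threshold (Angstrom).
#' @return Character vector of labels, one per residue.
#' @export
classify_ss <- function(conf, dihedrals = NULL, ca_dist_max = 7.0) {
  stopifnot(inherits(conf, "conformation"))
  if (is.null(dihedrals)) dihedrals <- backbone_dihedrals(conf)
  n <- nrow(dihedrals)
  helix <- .runs_at_least(.in_alphaR(dihedrals$phi, dihedrals$psi), 4L)
  sheet <- .runs_at_least(.in_beta(dihedrals$phi, dihedrals$psi), 2L) & !helix
  lab <- ifelse(helix, "helix", ifelse(sheet, "sheet", "coil"))
  CA <- atom_matrix(conf, "CA")
  if (n >= 4L) for (i in seq_len(n - 3L)) {
    if (any(is.na(CA[c(i, i + 3L), ]))) next
    if (vnorm(CA[i, ] - CA[i + 3L, ]) < ca_dist_max) {
      w <- i:(i + 3L)
      lab[w][lab[w] == "coil"] <- "turn"
    }
  }
  lab
}

#' Detect backbone hydrogen bonds
#'
#' Geometric criterion over all backbone donor (N-H) / acceptor (C=O)
#' pairs at sequence separation >= 2: O...N distance <= `hbond_ON_max`
#' and N-H...O angle >= `hbond_angle_min`. Proline cannot donate (no
#' amide H); a missing amide H is reconstructed in the C(prev)-N-CA
#' plane when possible, otherwise the residue is skipped.
#'
#' @param conf A [conformation()].
#' @param criteria A [turn_criteria()].
#' @return Data.frame with columns `donor`, `acceptor` (residue
#'   indices), `dist_ON` (Angstrom), `angle_NHO` (degrees).
#' @export
find_hbonds <- function(conf, criteria = turn_criteria()) {
  stopifnot(inherits(conf, "conformation"))
  n <- length(conf$peptide$residues)
  N <- atom_matrix(conf, "N"); CA <- atom_matrix(conf, "CA")
  C <- atom_matrix(conf, "C"); O <- atom_matrix(conf, "O")
  H <- atom_matrix(conf, "H")
  if (any(is.na(O[conf$usable, ])))
    warning("residues missing carbonyl O skipped", call. = FALSE)
  # reconstruct missing amide hydrogens where geometry allows
  if (n >= 2L) for (i in 2:n) {
    if (any(is.na(H[i, ])) && conf$peptide$residues[i] != "P" &&
        !any(is.na(N[i, ])) && !any(is.na(CA[i, ])) && !any(is.na(C[i - 1, ]))) {
      hdir <- -(unit(C[i - 1, ] - N[i, ]) + unit(CA[i, ] - N[i, ]))
      H[i, ] <- N[i, ] + 1.01 * unit(hdir)
    }
  }
  out <- list()
  for (d in seq_len(n)) {
    if (conf$peptide$residues[d] == "P") next
    if (any(is.na(N[d, ])) || any(is.na(H[d, ]))) next
    for (a in seq_len(n)) {
      if (abs(d - a) < 2L) next
      if (any(is.na(O[a, ]))) next
      dist <- vnorm(O[a, ] - N[d, ])
      if (dist > criteria$hbond_ON_max) next
      ang <- bond_angle(N[d, ], H[d, ], O[a, ])
      if (ang < criteria$hbond_angle_min) next
      out[[length(out) + 1L]] <- data.frame(
        donor = d, acceptor = a, dist_ON = dist, angle_NHO = ang)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), acceptor = integer(),
                      dist_ON = numeric(), angle_NHO = numeric()))
  do.call(rbind, out)
}

#' Detect beta-turn windows
#'
#' Scans every four-residue window i..i+3 and records the evidence for
#' each of the two classic criteria: an i(C=O) -> i+3(N-H) hydrogen bond
#' (criterion A) and C-alpha(i)-C-alpha(i+3) < `ca_dist_max`, strict
#' (criterion B). A window qualifies per `criteria$combine`; with
#' `exclude_helix`, windows whose inner residues (i+1, i+2) are
#' helix-labelled are rejected even when the geometry fits.
#'
#' @param conf A [conformation()].
#' @param criteria A [turn_criteria()].
#' @param ss Optional precomputed [classify_ss()] labels.
#' @return Data.frame of class `turn_records` with columns `start`
#'   (window i), `evidence` (`hbond`, `ca_distance` or `both`),
#'   `ca_dist`, `hbond_dist`, `hbond_angle`.
#' @examples
#' tc <- detect_beta_turns(make_motif("AAAAAAK", "beta_turn_II", 3))
#' @export
detect_beta_turns <- function(conf, criteria = turn_criteria(), ss = NULL) {
  stopifnot(inherits(conf, "conformation"))
  n <- length(conf$peptide$residues)
  empty <- structure(data.frame(start = integer(), evidence = character(),
                                ca_dist = numeric(), hbond_dist = numeric(),
                                hbond_angle = numeric()),
                     class = c("turn_records", "data.frame"))
  if (n < 4L) return(empty)
  if (is.null(ss)) ss <- classify_ss(conf, ca_dist_max = criteria$ca_dist_max)
  hb <- find_hbonds(conf, criteria)
  CA <- atom_matrix(conf, "CA")
  out <- list()
  for (i in seq_len(n - 3L)) {
    hbi <- hb[hb$acceptor == i & hb$donor == i + 3L, ]
    critA <- nrow(hbi) > 0L
    ca_dist <- if (any(is.na(CA[c(i, i + 3L), ]))) NA_real_
               else vnorm(CA[i, ] - CA[i + 3L, ])
    critB <- !is.na(ca_dist) && ca_dist < criteria$ca_dist_max
    hit <- if (criteria$combine == "either") critA || critB else critA && critB
    if (!hit) next
    if (criteria$exclude_helix && any(ss[i + 1:2] == "helix")) next
    out[[length(out) + 1L]] <- data.frame(
      start = i,
      evidence = if (critA && critB) "both"
                 else if (critA) "hbond" else "ca_distance",
      ca_dist = ca_dist,
      hbond_dist = if (critA) hbi$dist_ON[1] else NA_real_,
      hbond_angle = if (critA) hbi$angle_NHO[1] else NA_real_)
  }
  if (!length(out)) return(empty)
  structure(do.call(rbind, out), class = c("turn_records", "data.frame"))
}

#' Ensemble turn and beta-turn content
#'
#' Per frame: `turn_percent` is the percentage of residues labelled
#' `turn` by [classify_ss()]; `beta_turn_percent` is the percentage of
#' residues lying inside at least one qualifying beta-turn window from
#' [detect_beta_turns()] (`denominator = "residues"`, the default) or
#' the percentage of qualifying windows among all i..i+3 windows
#' (`denominator = "windows"`). Both are in \[0, 100\] and are averaged
#' over frames; neither bounds the other because the two counts use
#' different criteria.
#'
#' @param system A [peptide_system()].
#' @param criteria A [turn_criteria()].
#' @param denominator Counting mode, see above.
#' @return Object of class `turn_content`: list with `per_frame`
#'   (data.frame `frame`, `turn_percent`, `beta_turn_percent`),
#'   `turn_percent`, `beta_turn_percent` (ensemble means), `sd` of both.
#' @export
turn_content <- function(system, criteria = turn_criteria(),
                         denominator = c("residues", "windows")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(system, "peptide_system"))
  if (!length(system$frames) || !length(system$frames[[1]]))
    stop("empty system", call. = FALSE)
  per <- lapply(seq_along(system$frames), function(f) {
    frame <- system$frames[[f]]
    n_res <- 0L; n_turn <- 0L; n_in_windows <- 0L; n_windows <- 0L
    n_hit_windows <- 0L
    for (cf in frame) {
      n <- length(cf$peptide$residues)
      ss <- classify_ss(cf, ca_dist_max = criteria$ca_dist_max)
      rec <- detect_beta_turns(cf, criteria, ss = ss)
      n_res <- n_res + n
      n_turn <- n_turn + sum(ss == "turn")
      n_windows <- n_windows + max(0L, n - 3L)
      n_hit_windows <- n_hit_windows + nrow(rec)
      if (nrow(rec)) {
        res_in <- unique(unlist(lapply(rec$start, function(i) i:(i + 3L))))
        n_in_windows <- n_in_windows + length(res_in)
      }
    }
    beta_pct <- if (denominator == "residues") 100 * n_in_windows / n_res
                else if (n_windows) 100 * n_hit_windows / n_windows else 0
    data.frame(frame = f, turn_percent = 100 * n_turn / n_res,
               beta_turn_percent = beta_pct)
  })
  per <- do.call(rbind, per)
  structure(list(per_frame = per,
                 turn_percent = mean(per$turn_percent),
                 beta_turn_percent = mean(per$beta_turn_percent),
                 sd = c(turn = stats::sd(per$turn_percent),
                        beta_turn = stats::sd(per$beta_turn_percent)),
                 denominator = denominator, criteria = criteria),
            class = "turn_content")
}

#' @export
print.turn_content <- function(x, ...) {
  cat(sprintf("Turn content over %d frame(s) (denominator: %s)\n",
              nrow(x$per_frame), x$denominator))
  cat(sprintf("  turn:      %.1f%% (sd %.2f)\n", x$turn_percent,
              x$sd[["turn"]]))
  cat(sprintf("  beta-turn: %.1f%% (sd %.2f)\n", x$beta_turn_percent,
              x$sd[["beta_turn"]]))
  invisible(x)
}
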
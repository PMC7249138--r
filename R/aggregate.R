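# Multi-chain organisation: contact clustering, radius of gyration,
# amphiphilic radial ordering about a principal axis, and a coarse
# screened-free Coulomb interaction score between chains.

#' @keywords internal
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

#' Single-linkage contact clusters of a frame
#'
#' Two chains are in contact when their minimum heavy-atom distance is at
#' most `cutoff_A`; aggregates are the connected components of the
#' contact graph (single linkage, so contact is transitive across
#' members). Deterministic.
#'
#' @param frame A list of [conformation()] objects (one frame of a
#'   [peptide_system()]).
#' @param cutoff_A Contact cutoff in Angstrom (default 4.5, a typical
#'   heavy-atom contact definition).
#' @return Object of class `cluster_labeling`: list with `membership`
#'   (integer aggregate id per chain), `sizes` (chains per aggregate)
#'   and `cutoff_A`.
#' @export
contact_clusters <- function(frame, cutoff_A = 4.5) {
  if (inherits(frame, "peptide_system")) frame <- frame$frames[[1]]
  if (!length(frame)) stop("empty frame", call. = FALSE)
  stopifnot(cutoff_A > 0)
  n <- length(frame)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    adj[i, j] <- adj[j, i] <-
      min_interchain_dist(frame[[i]], frame[[j]]) <= cutoff_A
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  structure(list(membership = as.integer(comp$membership),
                 sizes = as.integer(comp$csize), cutoff_A = cutoff_A),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("%d chain(s) in %d aggregate(s) at cutoff %.1f A; sizes: %s\n",
              length(x$membership), length(x$sizes), x$cutoff_A,
              paste(sort(x$sizes, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Mass-weighted radius of gyration
#'
#' Root-mean-square (mass-weighted) distance of atoms from their centre
#' of mass. Invariant under rigid motion.
#'
#' @param x A [conformation()], a list of conformations, or a data.frame
#'   of atoms with `elem`, `x`, `y`, `z` columns.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(x) {
  at <- if (inherits(x, "conformation")) x$atoms
        else if (is.data.frame(x)) x
        else do.call(rbind, lapply(x, function(cf) cf$atoms))
  stopifnot(nrow(at) >= 1L)
  m <- .element_mass[at$elem]
  m[is.na(m)] <- 12.011
  xyz <- as.matrix(at[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
}

#' @keywords internal
principal_axis <- function(points) {
  cen <- colMeans(points)
  sv <- svd(sweep(points, 2, cen))
  if (sv$d[1] < 1e-9 || nrow(points) < 2L)
    stop("degenerate axis: no spread in the points", call. = FALSE)
  ax <- sv$v[, 1]
  # lexicographic sign convention for reproducibility
  nz <- which(abs(ax) > 1e-12)[1]
  if (ax[nz] < 0) ax <- -ax
  list(centre = cen, axis = ax)
}

#' @keywords internal
radial_dist <- function(points, centre, axis) {
  rel <- sweep(points, 2, centre)
  along <- rel %*% axis
  sqrt(pmax(0, rowSums(rel^2) - as.numeric(along)^2))
}

#' Amphiphilic radial ordering of an aggregate
#'
#' Projects hydrophobic (Ala CB) and hydrophilic (Lys NZ) marker atoms
#' onto the plane perpendicular to the aggregate axis (first principal
#' component of all C-alpha positions, or a supplied axis) and reports
#' mean radial distances per group plus the amphiphilic order
#' `mean_radial(Lys NZ) - mean_radial(Ala CB)` in Angstrom. Positive
#' order means a hydrophobic core with the lysines distributed outside.
#'
#' @param frame List of [conformation()] objects (or a
#'   [peptide_system()], first frame).
#' @param axis_mode `"principal"` (default; needs >= 3 chains) or
#'   `"given"`.
#' @param axis Unit axis vector when `axis_mode = "given"`.
#' @return List with `axis`, `centre`, `mean_radial_ala_cb`,
#'   `mean_radial_lys_nz` and `amphiphilic_order` (Angstrom).
#' @export
amphiphilic_profile <- function(frame, axis_mode = c("principal", "given"),
                                axis = NULL) {
  axis_mode <- match.arg(axis_mode)
  if (inherits(frame, "peptide_system")) frame <- frame$frames[[1]]
  if (axis_mode == "principal" && length(frame) < 3L)
    stop("principal-axis mode needs at least 3 chains", call. = FALSE)
  at <- do.call(rbind, lapply(frame, function(cf) cf$atoms))
  ca <- as.matrix(at[at$atom == "CA", c("x", "y", "z")])
  if (axis_mode == "principal") {
    pa <- principal_axis(ca)
  } else {
    stopifnot(!is.null(axis), length(axis) == 3L)
    pa <- list(centre = colMeans(ca), axis = unit(axis))
  }
  cb <- as.matrix(at[at$letter == "A" & at$atom == "CB",
                     c("x", "y", "z")])
  nz <- as.matrix(at[at$letter == "K" & at$atom == "NZ",
                     c("x", "y", "z")])
  r_cb <- if (nrow(cb)) mean(radial_dist(cb, pa$centre, pa$axis)) else NA_real_
  r_nz <- if (nrow(nz)) mean(radial_dist(nz, pa$centre, pa$axis)) else NA_real_
  list(axis = pa$axis, centre = pa$centre,
       mean_radial_ala_cb = r_cb, mean_radial_lys_nz = r_nz,
       amphiphilic_order = r_nz - r_cb)
}

#' @keywords internal
charge_site_atoms <- function(conf, pH, pka) {
  m <- protonation_model(conf$peptide, pka)
  s <- m$sites
  if (!nrow(s)) return(NULL)
  xyz <- matrix(NA_real_, nrow(s), 3)
  for (i in seq_len(nrow(s))) {
    v <- switch(
      s$site_kind[i],
      n_terminus = atom_xyz(conf, 1L, "N"),
      side_chain = {
        nz <- atom_xyz(conf, s$residue_index[i], "NZ")
        if (is.null(nz)) atom_xyz(conf, s$residue_index[i], "CB") else nz
      },
      c_terminus = {
        o <- atom_xyz(conf, s$residue_index[i], "O")
        oxt <- atom_xyz(conf, s$residue_index[i], "OXT")
        if (!is.null(o) && !is.null(oxt)) (o + oxt) / 2 else o
      })
    if (is.null(v) || any(is.na(v)))
      stop(sprintf("chain %s: cannot resolve %s site to an atom",
                   conf$chain_id, s$site_kind[i]), call. = FALSE)
    xyz[i, ] <- v
  }
  list(charge = site_charges_at(s, pH), xyz = xyz)
}

# Coulomb constant e^2/(4 pi eps0), in kJ/mol * nm per e^2.
#' @keywords internal
.ke_kj_nm <- 138.935458

#' Coarse pairwise electrostatic interaction score
#'
#' Sum of screened Coulomb terms q1*q2 / (4 pi eps0 eps_r r) over all
#' cross-chain pairs of charge sites, with fractional site charges from
#' the Henderson-Hasselbalch model at the given pH. Charges sit on
#' representative atoms: the N-terminal N, the Lys NZ pseudo-atom, and
#' the midpoint of the two carboxylate oxygens (the carbonyl O when OXT
#' is absent). Pairs beyond `cutoff_nm` are omitted. Positive scores are
#' net repulsive. This is a qualitative interaction score, not a force
#' field energy.
#'
#' @param chainA,chainB [conformation()] objects.
#' @param pH Solution pH.
#' @param pka A [pka_set()] or name.
#' @param dielectric Relative dielectric constant (default 78.5, bulk
#'   water).
#' @param cutoff_nm Pair distance cutoff in nm (default 1.4).
#' @return Score in kJ/mol (symmetric in its chain arguments).
#' @export
pair_electrostatic_score <- function(chainA, chainB, pH,
                                     pka = pka_set("bjellqvist"),
                                     dielectric = 78.5, cutoff_nm = 1.4) {
  sa <- charge_site_atoms(chainA, pH, pka)
  sb <- charge_site_atoms(chainB, pH, pka)
  if (is.null(sa) || is.null(sb)) return(0)
  e <- 0
  for (i in seq_along(sa$charge)) for (j in seq_along(sb$charge)) {
    r_nm <- vnorm(sa$xyz[i, ] - sb$xyz[j, ]) / 10
    if (r_nm > cutoff_nm || r_nm == 0) next
    e <- e + .ke_kj_nm * sa$charge[i] * sb$charge[j] / (dielectric * r_nm)
  }
  e
}

#' Full per-frame aggregate report
#'
#' Combines [contact_clusters()], per-aggregate [radius_of_gyration()]
#' and [amphiphilic_profile()] (principal axis where the aggregate
#' has at least 3 chains) with the matrix of
#' [pair_electrostatic_score()] values at one pH.
#'
#' @param frame List of [conformation()] objects (or a
#'   [peptide_system()], first frame).
#' @param cutoff_A Contact cutoff (Angstrom).
#' @param pH pH for the electrostatic scores.
#' @param pka A [pka_set()] or name.
#' @param dielectric,cutoff_nm Passed to [pair_electrostatic_score()].
#' @return Object of class `aggregate_report`: list with `clusters`,
#'   `aggregates` (data.frame: `id`, `size`, `rgyr_A`,
#'   `amphiphilic_order_A`), `electrostatic` (chain-pair score matrix,
#'   kJ/mol) and `pH`.
#' @export
aggregate_report <- function(frame, cutoff_A = 4.5, pH = 7,
                             pka = pka_set("bjellqvist"),
                             dielectric = 78.5, cutoff_nm = 1.4) {
  if (inherits(frame, "peptide_system")) frame <- frame$frames[[1]]
  cl <- contact_clusters(frame, cutoff_A)
  agg <- do.call(rbind, lapply(seq_along(cl$sizes), function(id) {
    members <- frame[cl$membership == id]
    order_A <- if (length(members) >= 3L)
      tryCatch(amphiphilic_profile(members)$amphiphilic_order,
               error = function(e) NA_real_)
      else NA_real_
    data.frame(id = id, size = length(members),
               rgyr_A = radius_of_gyration(members),
               amphiphilic_order_A = order_A)
  }))
  n <- length(frame)
  es <- matrix(0, n, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    es[i, j] <- es[j, i] <- pair_electrostatic_score(
      frame[[i]], frame[[j]], pH, pka, dielectric, cutoff_nm)
  }
  structure(list(clusters = cl, aggregates = agg, electrostatic = es,
                 pH = pH),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  print(x$clusters)
  print(x$aggregates, row.names = FALSE)
  cat(sprintf("total electrostatic score at pH %g: %+.3f kJ/mol\n",
              x$pH, sum(x$electrostatic) / 2))
  invisible(x)
}
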
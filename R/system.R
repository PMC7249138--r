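# Multi-chain system generation: dispersed random packing and an
# idealised micellar arrangement with the hydrophobic Ala end inward and
# the Lys side chain outward.

#' @keywords internal
transform_conf <- function(conf, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  conf$atoms$x <- xyz[, 1]; conf$atoms$y <- xyz[, 2]; conf$atoms$z <- xyz[, 3]
  conf
}

#' @keywords internal
min_interchain_dist <- function(a, b) {
  xa <- heavy_xyz(a); xb <- heavy_xyz(b)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

#' @keywords internal
build_template_chain <- function(p, motif, seed, geom, chain_id,
                                 turn_position = 2L) {
  if (identical(motif, "coil"))
    sample_coil(p, seed = seed, geom = geom, chain_id = chain_id)
  else make_motif(p, motif, turn_position = turn_position, geom = geom,
                  chain_id = chain_id)
}

#' Generate a multi-chain peptide system
#'
#' The synthetic stand-in for simulation snapshots of many short chains
#' in a box. `"dispersed"` placement applies a random rigid-body rotation
#' and translation to every chain, rejecting placements whose minimum
#' heavy-atom distance to any placed chain falls below `min_dist_A`.
#' `"micellar"` placement arranges chains around a central z-axis with
#' the N-terminal (Ala) end pointing inward and the C-terminal Lys side
#' chain outward, producing a hydrophobic core / hydrophilic shell whose
#' amphiphilic radial order is positive by construction.
#'
#' @param x A [peptide()] or sequence string.
#' @param n_chains Number of chains (>= 1).
#' @param box_nm Cubic box edge in nm (default 8, i.e. a 512 nm^3 box).
#' @param placement `"dispersed"` or `"micellar"`.
#' @param min_dist_A Minimum inter-chain heavy-atom distance (Angstrom)
#'   enforced for dispersed placement.
#' @param seed Integer seed (mandatory; all randomness derives from it).
#' @param per_chain_motif Character vector (recycled over chains) of
#'   motif names from [motif_library()] or `"coil"`; default `"coil"`.
#' @param turn_position Window start passed to [make_motif()] for turn
#'   motifs.
#' @param n_frames Number of independently generated frames.
#' @param max_attempts Rejection-sampling cap per chain for dispersed
#'   placement.
#' @param geom A [geometry_params()].
#' @return A [peptide_system()].
#' @examples
#' sys <- make_system("AAAAAAK", n_chains = 5, seed = 1)
#' @export
make_system <- function(x, n_chains, box_nm = 8,
                        placement = c("dispersed", "micellar"),
                        min_dist_A = 4, seed, per_chain_motif = "coil",
                        turn_position = 2L, n_frames = 1L,
                        max_attempts = 2000L, geom = geometry_params()) {
  placement <- match.arg(placement)
  p <- as_peptide(x)
  stopifnot(n_chains >= 1L, box_nm > 0, n_frames >= 1L)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  motifs <- rep_len(per_chain_motif, n_chains)
  ids <- chain_id_pool(n_chains)
  box_A <- box_nm * 10
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    chains <- lapply(seq_len(n_chains), function(k)
      build_template_chain(p, motifs[k],
                           seed = sample.int(.Machine$integer.max, 1),
                           geom = geom, chain_id = ids[k],
                           turn_position = turn_position))
    # centre each chain on its heavy-atom centroid before placing
    chains <- lapply(chains, function(cf)
      transform_conf(cf, shift = -colMeans(heavy_xyz(cf))))
    if (placement == "dispersed")
      place_dispersed(chains, box_A, min_dist_A, max_attempts)
    else
      place_micellar(chains, box_A)
  }))
  peptide_system(frames, box_nm = rep(box_nm, 3))
}

#' @keywords internal
place_dispersed <- function(chains, box_A, min_dist_A, max_attempts) {
  placed <- list()
  margin <- 5  # keep centroids off the walls
  for (cf in chains) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- transform_conf(cf, R = random_rotation(),
                             shift = stats::runif(3, margin, box_A - margin))
      clash <- FALSE
      for (q in placed)
        if (min_interchain_dist(cand, q) < min_dist_A) { clash <- TRUE; break }
      if (!clash) { placed[[length(placed) + 1L]] <- cand; ok <- TRUE; break }
    }
    if (!ok)
      stop("packing failed: attempt cap exceeded; use a larger box or fewer chains",
           call. = FALSE)
  }
  placed
}

#' @keywords internal
place_micellar <- function(chains, box_A) {
  n <- length(chains)
  centre <- rep(box_A / 2, 3)
  r_inner <- 3  # Angstrom: radius at which the Ala end sits
  out <- vector("list", n)
  for (k in seq_len(n)) {
    cf <- chains[[k]]
    ca <- atom_matrix(cf, "CA")
    long_axis <- unit(ca[nrow(ca), ] - ca[1, ])  # N-term -> C-term
    theta <- 2 * pi * (k - 1) / n + stats::runif(1, -0.1, 0.1)
    u <- c(cos(theta), sin(theta), 0)            # outward radial direction
    R <- rotation_between(long_axis, u)
    cf <- transform_conf(cf, R = R)
    # after rotation, put the first CA at radius r_inner (with jitter)
    ca1 <- as.numeric(atom_matrix(cf, "CA")[1, ])
    z <- stats::runif(1, -4, 4)
    target <- centre + (r_inner + stats::runif(1, 0, 1)) * u + c(0, 0, z)
    out[[k]] <- transform_conf(cf, shift = target - ca1)
  }
  out
}
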
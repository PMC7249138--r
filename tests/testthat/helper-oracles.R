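# Independent brute-force oracles and fixture builders. Everything here
# recomputes quantities from raw coordinates/closed forms without going
# through the package code paths it is used to check.

o_norm <- function(v) sqrt(sum(v^2))

o_angle <- function(a, b, c) {
  v1 <- (a - b) / o_norm(a - b); v2 <- (c - b) / o_norm(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

# xyz of one named atom in one residue of a conformation, or NULL
o_xyz <- function(conf, res, name) {
  i <- which(conf$atoms$res == res & conf$atoms$atom == name)
  if (!length(i)) return(NULL)
  as.numeric(conf$atoms[i[1], c("x", "y", "z")])
}

# Brute-force beta-turn scan: for every i..i+3 window recompute both
# criteria directly from coordinates (hydrogen bond i(C=O) -> i+3(N-H)
# and the C-alpha distance), no helix exclusion.
oracle_beta_turn_starts <- function(conf, ca_max = 7.0, on_max = 3.5,
                                    ang_min = 120, combine = "either") {
  n <- length(conf$peptide$residues)
  hits <- integer()
  if (n < 4L) return(hits)
  for (i in seq_len(n - 3L)) {
    O <- o_xyz(conf, i, "O")
    Nd <- o_xyz(conf, i + 3L, "N")
    Hd <- o_xyz(conf, i + 3L, "H")
    critA <- FALSE
    if (!is.null(O) && !is.null(Nd) && !is.null(Hd) &&
        conf$peptide$residues[i + 3L] != "P")
      critA <- o_norm(O - Nd) <= on_max && o_angle(Nd, Hd, O) >= ang_min
    ca1 <- o_xyz(conf, i, "CA"); ca2 <- o_xyz(conf, i + 3L, "CA")
    critB <- !is.null(ca1) && !is.null(ca2) && o_norm(ca1 - ca2) < ca_max
    hit <- if (combine == "either") critA || critB else critA && critB
    if (hit) hits <- c(hits, i)
  }
  hits
}

# Brute-force single-linkage components via BFS over an adjacency
# computed with an independent double-loop distance scan.
oracle_components <- function(frame, cutoff) {
  n <- length(frame)
  heavy <- lapply(frame, function(cf)
    as.matrix(cf$atoms[cf$atoms$elem != "H", c("x", "y", "z")]))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dmin <- Inf
    for (a in seq_len(nrow(heavy[[i]])))
      dmin <- min(dmin, sqrt(rowSums(sweep(heavy[[j]], 2,
                                           heavy[[i]][a, ])^2)))
    adj[i, j] <- dmin <= cutoff
  }
  comp <- rep(NA_integer_, n)
  id <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    id <- id + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- id
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# random peptide chain with arbitrary dihedrals (fixed seed outside)
random_chain <- function(n = 7, letters_pool = c("A", "K", "G", "S", "V")) {
  seq <- paste(sample(letters_pool, n, replace = TRUE), collapse = "")
  phi <- runif(n, -179, 179)
  psi <- runif(n, -179, 179)
  build_chain(seq, list(phi = phi, psi = psi))
}

# point-like single-residue conformation at a given offset: atoms packed
# within 0.1 A so inter-"chain" distances are controlled exactly
point_chain <- function(offset, chain_id = "A") {
  at <- data.frame(res = 1L, letter = "A",
                   atom = c("N", "CA", "C", "O"),
                   x = offset[1] + c(0, 0.03, 0.06, 0.09),
                   y = offset[2], z = offset[3],
                   stringsAsFactors = FALSE)
  conformation(at, chain_id = chain_id)
}

rotate_conf <- function(cf, R, shift = c(0, 0, 0)) {
  xyz <- as.matrix(cf$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  cf$atoms$x <- xyz[, 1]; cf$atoms$y <- xyz[, 2]; cf$atoms$z <- xyz[, 3]
  cf
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
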
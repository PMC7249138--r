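# In-memory coordinate model and fixed-width PDB/GRO readers/writers.
#
# A `conformation` is one peptide chain: a data.frame of atoms (columns
# res, letter, atom, elem, x, y, z; coordinates in Angstrom) plus the
# peptide spec and a per-residue `usable` flag (backbone N, CA, C, O all
# present). A `peptide_system` is a list of frames, each a list of
# conformations, with an optional orthorhombic box in nm.

#' @keywords internal
.backbone_atoms <- c("N", "CA", "C", "O")

#' @keywords internal
element_of <- function(atom_name) {
  nm <- gsub("[0-9']", "", atom_name)
  substr(nm, 1, 1)
}

#' Construct a single-chain conformation
#'
#' @param atoms Data.frame with columns `res` (1-based residue index),
#'   `letter` (one-letter residue code), `atom` (atom name), `x`, `y`,
#'   `z` (Angstrom); an `elem` column is derived when absent.
#' @param peptide The [peptide()] the chain instantiates; derived from
#'   `atoms$letter` when `NULL`.
#' @param chain_id Single-character chain label.
#' @return An object of class `conformation`.
#' @export
conformation <- function(atoms, peptide = NULL, chain_id = "A") {
  stopifnot(is.data.frame(atoms),
            all(c("res", "letter", "atom", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite", call. = FALSE)
  if (is.null(atoms$elem)) atoms$elem <- element_of(atoms$atom)
  res_ids <- sort(unique(atoms$res))
  if (!identical(as.integer(res_ids), seq_along(res_ids)))
    stop("residue indices must be consecutive from 1", call. = FALSE)
  letters1 <- vapply(res_ids, function(r) atoms$letter[atoms$res == r][1], "")
  if (is.null(peptide)) peptide <- peptide(paste(letters1, collapse = ""))
  if (!identical(letters1, peptide$residues))
    stop("atom residue letters do not match the peptide sequence",
         call. = FALSE)
  usable <- vapply(res_ids, function(r)
    all(.backbone_atoms %in% atoms$atom[atoms$res == r]), logical(1))
  structure(list(chain_id = chain_id, peptide = peptide,
                 atoms = atoms, usable = usable),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("Conformation %s: %s, %d atoms, %d/%d residues usable\n",
              x$chain_id, x$peptide$sequence, nrow(x$atoms),
              sum(x$usable), length(x$usable)))
  invisible(x)
}

# Coordinates of a named atom in a residue, or NULL if absent.
#' @keywords internal
atom_xyz <- function(conf, res, name) {
  i <- which(conf$atoms$res == res & conf$atoms$atom == name)
  if (!length(i)) return(NULL)
  as.numeric(conf$atoms[i[1], c("x", "y", "z")])
}

# n_res x 3 matrix of one atom type per residue (NA rows when absent).
#' @keywords internal
atom_matrix <- function(conf, name) {
  n <- length(conf$peptide$residues)
  m <- matrix(NA_real_, n, 3)
  sel <- conf$atoms[conf$atoms$atom == name, ]
  m[sel$res, ] <- as.matrix(sel[, c("x", "y", "z")])
  m
}

#' @keywords internal
heavy_xyz <- function(conf) {
  as.matrix(conf$atoms[conf$atoms$elem != "H", c("x", "y", "z")])
}

#' Construct a multi-chain, multi-frame peptide system
#'
#' @param frames List of frames; each frame is a list of [conformation()]
#'   objects. Every frame must have the same chain composition.
#' @param box_nm Optional orthorhombic box edge lengths in nm (length 1
#'   or 3).
#' @return An object of class `peptide_system`.
#' @export
peptide_system <- function(frames, box_nm = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (inherits(frames[[1]], "conformation")) frames <- list(frames)
  n_chain <- length(frames[[1]])
  seqs <- vapply(frames[[1]], function(cf) cf$peptide$sequence, "")
  for (fr in frames) {
    if (length(fr) != n_chain ||
        !identical(vapply(fr, function(cf) cf$peptide$sequence, ""), seqs))
      stop("all frames must have identical chain composition", call. = FALSE)
  }
  if (!is.null(box_nm)) {
    if (length(box_nm) == 1L) box_nm <- rep(box_nm, 3)
    stopifnot(length(box_nm) == 3L, all(box_nm > 0))
  }
  structure(list(frames = frames, box_nm = box_nm),
            class = "peptide_system")
}

#' @export
print.peptide_system <- function(x, ...) {
  cat(sprintf("Peptide system: %d frame(s) x %d chain(s)\n",
              length(x$frames), length(x$frames[[1]])))
  if (!is.null(x$box_nm))
    cat(sprintf("  box: %.2f x %.2f x %.2f nm\n",
                x$box_nm[1], x$box_nm[2], x$box_nm[3]))
  invisible(x)
}

#' @keywords internal
chain_id_pool <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  pool[(seq_len(n) - 1L) %% length(pool) + 1L]
}

#' Write a peptide system as a multi-model PDB file
#'
#' Fixed-width ATOM records, one MODEL/ENDMDL block per frame, TER after
#' each chain, CRYST1 when a box is present (nm converted to Angstrom).
#'
#' @param system A [peptide_system()] (or a single [conformation()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path) {
  if (inherits(system, "conformation")) system <- peptide_system(list(list(system)))
  stopifnot(inherits(system, "peptide_system"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(system$box_nm))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      system$box_nm[1] * 10, system$box_nm[2] * 10, system$box_nm[3] * 10,
      90, 90, 90), con)
  multi <- length(system$frames) > 1L
  ids <- chain_id_pool(length(system$frames[[1]]))
  for (f in seq_along(system$frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (k in seq_along(system$frames[[f]])) {
      cf <- system$frames[[f]][[k]]
      at <- cf$atoms
      res3 <- .aa_three[at$letter]
      for (i in seq_len(nrow(at))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, at$atom[i], " ", res3[i], ids[k], at$res[i],
          " ", at$x[i], at$y[i], at$z[i], 1, 0, at$elem[i]), con)
      }
      writeLines(sprintf("TER   %5d      %3s %1s%4d",
                         (serial + 1L) %% 100000L,
                         res3[nrow(at)], ids[k], at$res[nrow(at)]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (multi-model) PDB file into a peptide system
#'
#' One frame per MODEL block (a single frame when no MODEL records are
#' present); chains split on TER records and chain-identifier changes.
#' Alternate locations other than blank/'A' are skipped; insertion codes
#' are not supported. Residues missing any backbone atom (N, CA, C, O)
#' are flagged unusable with a warning.
#'
#' @param path PDB file path.
#' @return A [peptide_system()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  box <- NULL
  frames <- list()
  cur_frame <- list()       # list of per-chain atom-row lists
  cur_atoms <- list()
  cur_chain <- NULL
  flush_chain <- function() {
    if (length(cur_atoms)) {
      cur_frame[[length(cur_frame) + 1L]] <<- do.call(rbind, cur_atoms)
      cur_atoms <<- list()
    }
    cur_chain <<- NULL
  }
  flush_frame <- function() {
    flush_chain()
    if (length(cur_frame)) {
      frames[[length(frames) + 1L]] <<- cur_frame
      cur_frame <<- list()
    }
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    rec <- substr(line, 1, 6)
    if (rec == "CRYST1") {
      box <- as.numeric(c(substr(line, 7, 15), substr(line, 16, 24),
                          substr(line, 25, 33))) / 10
    } else if (substr(line, 1, 5) == "MODEL") {
      flush_frame()
    } else if (rec == "ENDMDL") {
      flush_frame()
    } else if (substr(line, 1, 3) == "TER") {
      flush_chain()
    } else if (rec == "ATOM  " || rec == "HETATM") {
      altloc <- substr(line, 17, 17)
      if (!(altloc %in% c(" ", "A"))) next
      if (substr(line, 27, 27) != " ")
        stop(sprintf("insertion codes are not supported (line %d)", ln),
             call. = FALSE)
      xyz <- suppressWarnings(as.numeric(c(
        substr(line, 31, 38), substr(line, 39, 46), substr(line, 47, 54))))
      resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
      if (any(is.na(xyz)) || is.na(resno))
        stop(sprintf("malformed ATOM record at line %d", ln), call. = FALSE)
      chain <- substr(line, 22, 22)
      if (!is.null(cur_chain) && chain != cur_chain) flush_chain()
      cur_chain <- chain
      res3 <- trimws(substr(line, 18, 20))
      if (!(res3 %in% names(.aa_one)))
        stop(sprintf("unknown residue '%s' at line %d", res3, ln),
             call. = FALSE)
      elem <- trimws(substr(line, 77, 78))
      atom <- trimws(substr(line, 13, 16))
      cur_atoms[[length(cur_atoms) + 1L]] <- data.frame(
        res = resno, letter = .aa_one[[res3]], atom = atom,
        elem = if (nzchar(elem)) elem else element_of(atom),
        x = xyz[1], y = xyz[2], z = xyz[3],
        chain = chain, stringsAsFactors = FALSE)
    }
  }
  flush_frame()
  if (!length(frames)) stop("no ATOM records found in ", path, call. = FALSE)
  sys_frames <- lapply(frames, function(fr) {
    lapply(fr, function(at) {
      # renumber residues 1..n in order of appearance (file order preserved)
      ids <- unique(at$res)
      at$res <- match(at$res, ids)
      cf <- conformation(at[, c("res", "letter", "atom", "elem",
                                "x", "y", "z")],
                         chain_id = at$chain[1])
      if (!all(cf$usable))
        warning(sprintf(
          "chain %s: %d residue(s) missing backbone atoms, flagged unusable",
          cf$chain_id, sum(!cf$usable)), call. = FALSE)
      cf
    })
  })
  peptide_system(sys_frames, box_nm = box)
}

#' Write a single-frame system as a GROMACS GRO file
#'
#' Coordinates converted Angstrom to nm with the format's 3-decimal
#' precision; the box line is written from `box_nm` (zeros when absent).
#'
#' @param system A [peptide_system()] with one frame, or a
#'   [conformation()].
#' @param path Output file path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_gro <- function(system, path, title = "generated by pepassembly") {
  if (inherits(system, "conformation")) system <- peptide_system(list(list(system)))
  if (length(system$frames) != 1L)
    stop("GRO files hold a single configuration; system has multiple frames",
         call. = FALSE)
  frame <- system$frames[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(sprintf("%5d", sum(vapply(frame, function(cf) nrow(cf$atoms),
                                       integer(1)))), con)
  serial <- 0L; res_off <- 0L
  for (cf in frame) {
    at <- cf$atoms
    res3 <- .aa_three[at$letter]
    for (i in seq_len(nrow(at))) {
      serial <- serial + 1L
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         (at$res[i] + res_off) %% 100000L, res3[i],
                         at$atom[i], serial %% 100000L,
                         at$x[i] / 10, at$y[i] / 10, at$z[i] / 10), con)
    }
    res_off <- res_off + max(at$res)
  }
  box <- if (is.null(system$box_nm)) c(0, 0, 0) else system$box_nm
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  invisible(path)
}

#' Read a single-configuration GRO file
#'
#' Fixed-width fields; coordinates converted nm to Angstrom; trailing
#' velocity columns, when present, are ignored. Chains are split where
#' the residue number decreases (GRO has no chain identifiers).
#'
#' @param path GRO file path.
#' @return A [peptide_system()] with one frame.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file", call. = FALSE)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || length(lines) < 2L + natoms + 1L)
    stop("malformed GRO file: bad atom count", call. = FALSE)
  rows <- vector("list", natoms)
  for (i in seq_len(natoms)) {
    line <- lines[2L + i]
    resno <- suppressWarnings(as.integer(substr(line, 1, 5)))
    res3 <- trimws(substr(line, 6, 10))
    atom <- trimws(substr(line, 11, 15))
    xyz <- suppressWarnings(as.numeric(c(
      substr(line, 21, 28), substr(line, 29, 36), substr(line, 37, 44))))
    if (is.na(resno) || any(is.na(xyz)))
      stop(sprintf("malformed GRO atom line %d", 2L + i), call. = FALSE)
    if (!(res3 %in% names(.aa_one)))
      stop(sprintf("unknown residue '%s' at line %d", res3, 2L + i),
           call. = FALSE)
    rows[[i]] <- data.frame(res = resno, letter = .aa_one[[res3]],
                            atom = atom, elem = element_of(atom),
                            x = xyz[1] * 10, y = xyz[2] * 10, z = xyz[3] * 10,
                            stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  box <- suppressWarnings(as.numeric(
    strsplit(trimws(lines[2L + natoms + 1L]), "\\s+")[[1]]))[1:3]
  if (any(is.na(box))) box <- NULL else if (all(box == 0)) box <- NULL
  # chain break where residue numbering restarts (decreases)
  breaks <- c(1L, which(diff(at$res) < 0) + 1L)
  ends <- c(breaks[-1] - 1L, nrow(at))
  ids <- chain_id_pool(length(breaks))
  chains <- lapply(seq_along(breaks), function(k) {
    sub <- at[breaks[k]:ends[k], ]
    sub$res <- match(sub$res, unique(sub$res))
    conformation(sub, chain_id = ids[k])
  })
  peptide_system(list(chains), box_nm = box)
}
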
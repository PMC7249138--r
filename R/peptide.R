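# Amino-acid identity tables shared across the package.

#' @keywords internal
.aa_alphabet <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @keywords internal
.aa_three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' @keywords internal
.aa_one <- stats::setNames(names(.aa_three), .aa_three)

# Residue (monomer) masses in g/mol: the mass of the amino acid minus one
# water, i.e. the in-chain repeating unit. Standard average and
# monoisotopic tables as used by protein mass calculators.
#' @keywords internal
.aa_mass_average <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' @keywords internal
.aa_mass_mono <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

# Terminal group masses. A free N-terminus contributes H, a free C-terminus
# OH (together one water). Acetyl (CH3CO-) and amide (-NH2) caps replace
# those groups.
#' @keywords internal
.terminal_mass <- list(
  average = c(h = 1.00794, oh = 17.00734, acetyl = 43.04522, amide = 16.02258),
  monoisotopic = c(h = 1.007825, oh = 17.002740, acetyl = 43.018390,
                   amide = 16.018724))

#' Define a peptide: sequence plus termini blocking state
#'
#' The chemical identity every other computation derives from. `A6K`
#' denotes the heptapeptide Ala6-Lys; "uncapped" (`n_term = "free"`,
#' `c_term = "free"`) means a free amine N-terminus and free carboxyl
#' C-terminus (H2N-AAAAAAK-OH), so both termini are ionizable.
#'
#' @param sequence One-letter amino-acid string (20-residue alphabet).
#' @param n_term `"free"` for an ionizable alpha-amino group, `"blocked"`
#'   for an acetylated (non-ionizable) N-terminus.
#' @param c_term `"free"` for an ionizable carboxyl group, `"blocked"`
#'   for an amidated C-terminus.
#' @return An object of class `peptide_spec`.
#' @examples
#' a6k <- peptide("AAAAAAK")           # uncapped, both termini free
#' peptide("AAAAAAK", n_term = "blocked", c_term = "blocked")
#' @export
peptide <- function(sequence, n_term = c("free", "blocked"),
                    c_term = c("free", "blocked")) {
  n_term <- match.arg(n_term)
  c_term <- match.arg(c_term)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a non-empty character string", call. = FALSE)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(letters1 %in% .aa_alphabet))
  if (length(bad))
    stop(sprintf("unknown residue letter '%s' at position %d",
                 letters1[bad[1]], bad[1]), call. = FALSE)
  structure(
    list(sequence = paste(letters1, collapse = ""),
         residues = letters1,
         n_term_free = n_term == "free",
         c_term_free = c_term == "free"),
    class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  nt <- if (x$n_term_free) "H2N-" else "Ac-"
  ct <- if (x$c_term_free) "-OH" else "-NH2"
  cat(sprintf("Peptide %s%s%s (%d residues)\n", nt, x$sequence, ct,
              length(x$residues)))
  invisible(x)
}

#' @keywords internal
as_peptide <- function(x) {
  if (inherits(x, "peptide_spec")) return(x)
  if (is.character(x) && length(x) == 1L) return(peptide(x))
  stop("expected a 'peptide_spec' or a sequence string", call. = FALSE)
}

#' Molecular mass of a peptide
#'
#' Sum of residue (monomer) masses plus terminal groups: free termini add
#' one water in total (H at N, OH at C); blocked termini add the acetyl and
#' amide cap masses instead. Uncapped A6K gives 572.66 g/mol (average),
#' commonly quoted rounded as 573 g/mol.
#'
#' @param x A [peptide()] or sequence string.
#' @param mode `"average"` (default) or `"monoisotopic"` mass table.
#' @return Mass in g/mol.
#' @examples
#' molecular_weight(peptide("AAAAAAK"))        # 572.66
#' molecular_weight("G")                       # 75.07, free glycine
#' @export
molecular_weight <- function(x, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  p <- as_peptide(x)
  tab <- if (mode == "average") .aa_mass_average else .aa_mass_mono
  term <- .terminal_mass[[mode]]
  sum(tab[p$residues]) +
    (if (p$n_term_free) term[["h"]] else term[["acetyl"]]) +
    (if (p$c_term_free) term[["oh"]] else term[["amide"]])
}
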
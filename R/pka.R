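# pKa tables for ionizable groups of free peptides.

# Bjellqvist table as used by the ExPAsy Compute pI/Mw tool. N-terminal
# pKa depends on the first residue; C-terminal carboxyl has a generic
# value with side-chain-specific entries for terminal Asp/Glu handled via
# the side-chain table (the terminal carboxyl itself stays generic).
#' @keywords internal
.pka_bjellqvist <- list(
  name = "bjellqvist",
  n_term = c(default = 7.50, A = 7.59, M = 7.00, S = 6.93, P = 8.36,
             T = 6.82, V = 7.44, E = 7.70, G = 7.50),
  c_term = c(default = 3.55),
  side_chain = c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00,
                 R = 12.00, Y = 10.00))

#' @keywords internal
.side_chain_polarity <- c(C = "acid", D = "acid", E = "acid", Y = "acid",
                          H = "base", K = "base", R = "base")

#' pKa set for ionizable peptide groups
#'
#' Returns a named pKa table covering the C-terminal carboxyl, the
#' N-terminal amine of every residue type, and the ionizable side chains
#' (D, E, H, C, Y, K, R). The default `"bjellqvist"` set is the table
#' behind the ExPAsy Compute pI/Mw tool (C-terminus 3.55, N-terminal Ala
#' 7.59, Lys side chain 10.00).
#'
#' @param name Name of a bundled set (currently `"bjellqvist"`).
#' @return An object of class `pka_set` with elements `name`, `n_term`,
#'   `c_term` and `side_chain` (named numeric vectors; `n_term`/`c_term`
#'   carry a `default` entry used when no residue-specific value exists).
#' @seealso [read_pka_set()] for user overrides from a file.
#' @export
pka_set <- function(name = "bjellqvist") {
  if (inherits(name, "pka_set")) return(name)
  if (identical(name, "bjellqvist"))
    return(structure(.pka_bjellqvist, class = "pka_set"))
  stop(sprintf("unknown pKa set '%s'", name), call. = FALSE)
}

#' @export
print.pka_set <- function(x, ...) {
  cat(sprintf("pKa set '%s'\n", x$name))
  cat(sprintf("  C-terminus: %.2f\n", x$c_term[["default"]]))
  cat(sprintf("  N-terminus (default): %.2f\n", x$n_term[["default"]]))
  sc <- paste(sprintf("%s %.2f", names(x$side_chain), x$side_chain),
              collapse = ", ")
  cat("  side chains:", sc, "\n")
  invisible(x)
}

#' Read a pKa override table from a two-column file
#'
#' The file is whitespace- or comma-separated with two columns: a site key
#' and a pKa. Keys are `n_term`, `c_term`, `n_term:X` (N-terminal value for
#' residue X) or a one-letter residue code for a side chain (e.g. `K`).
#' Unlisted sites keep the values of `base` (default Bjellqvist).
#'
#' @param path File path.
#' @param base pKa set to override (see [pka_set()]).
#' @return A `pka_set`.
#' @export
read_pka_set <- function(path, base = pka_set("bjellqvist")) {
  base <- pka_set(base)
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#",
                           col.names = c("key", "pka"),
                           colClasses = c("character", "numeric"))
  for (i in seq_len(nrow(tab))) {
    key <- tab$key[i]; val <- tab$pka[i]
    if (!is.finite(val) || val <= 0 || val >= 14)
      stop(sprintf("pKa for '%s' must lie in (0, 14)", key), call. = FALSE)
    if (key == "n_term") base$n_term[["default"]] <- val
    else if (key == "c_term") base$c_term[["default"]] <- val
    else if (startsWith(key, "n_term:"))
      base$n_term[[sub("^n_term:", "", key)]] <- val
    else if (key %in% names(.side_chain_polarity))
      base$side_chain[[key]] <- val
    else stop(sprintf("unknown pKa site key '%s'", key), call. = FALSE)
  }
  base$name <- paste0(base$name, "+overrides")
  base
}

#' @keywords internal
lookup_pka <- function(set, kind, residue) {
  tab <- set[[kind]]
  if (!is.null(tab[residue]) && !is.na(tab[residue])) tab[[residue]]
  else tab[["default"]]
}

#' Enumerate the ionizable sites of a peptide
#'
#' One site per free terminus plus one per ionizable side chain (D, E, H,
#' C, Y, K, R), in N-to-C order; blocked termini contribute no site.
#' Uncapped A6K has exactly three sites: the N-terminal amine (base), the
#' Lys-7 side chain (base) and the C-terminal carboxyl (acid).
#'
#' @param x A [peptide()] or sequence string.
#' @param pka A [pka_set()] or set name.
#' @return A data.frame with columns `site_kind` (`n_terminus`,
#'   `side_chain`, `c_terminus`), `residue_index` (1-based), `residue`
#'   (one-letter code), `pKa` and `polarity` (`acid`/`base`).
#' @examples
#' ionizable_sites(peptide("AAAAAAK"))
#' @export
ionizable_sites <- function(x, pka = pka_set("bjellqvist")) {
  p <- as_peptide(x)
  set <- pka_set(pka)
  n <- length(p$residues)
  rows <- list()
  if (p$n_term_free)
    rows[[length(rows) + 1L]] <- data.frame(
      site_kind = "n_terminus", residue_index = 1L, residue = p$residues[1],
      pKa = lookup_pka(set, "n_term", p$residues[1]), polarity = "base",
      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- p$residues[i]
    if (r %in% names(.side_chain_polarity))
      rows[[length(rows) + 1L]] <- data.frame(
        site_kind = "side_chain", residue_index = i, residue = r,
        pKa = set$side_chain[[r]], polarity = .side_chain_polarity[[r]],
        stringsAsFactors = FALSE)
  }
  if (p$c_term_free)
    rows[[length(rows) + 1L]] <- data.frame(
      site_kind = "c_terminus", residue_index = n, residue = p$residues[n],
      pKa = lookup_pka(set, "c_term", p$residues[n]), polarity = "acid",
      stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(site_kind = character(), residue_index = integer(),
                      residue = character(), pKa = numeric(),
                      polarity = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
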
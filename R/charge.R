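# Henderson-Hasselbalch protonation model for free peptides.
#
# Each ionizable group carries a fractional charge determined only by pH
# and its pKa:
#   base:  q = +1 / (1 + 10^(pH - pKa))
#   acid:  q = -1 / (1 + 10^(pKa - pH))
# and the peptide net charge is the sum over sites. Both forms are
# strictly decreasing in pH, so the net charge is too, which makes the
# isoelectric point a simple bisection root.

#' Fractional charge of one ionizable site
#'
#' @param pKa Acid dissociation exponent of the site.
#' @param polarity `"acid"` (charge in \[-1, 0\]) or `"base"` (charge in
#'   \[0, +1\]).
#' @param pH Solution pH, in \[0, 14\]; vectorized.
#' @return Fractional charge in elementary-charge units (e).
#' @examples
#' fractional_charge(10, "base", 10)   # +0.5 at the pKa
#' fractional_charge(3.55, "acid", 2)  # -0.0274: carboxyl mostly neutral
#' @export
fractional_charge <- function(pKa, polarity = c("acid", "base"), pH) {
  polarity <- match.arg(polarity)
  if (any(!is.finite(pH)) || any(pH < 0) || any(pH > 14))
    stop("pH must lie in [0, 14]", call. = FALSE)
  if (polarity == "base") 1 / (1 + 10^(pH - pKa))
  else -1 / (1 + 10^(pKa - pH))
}

#' @keywords internal
site_charges_at <- function(sites, pH) {
  vapply(seq_len(nrow(sites)), function(i)
    fractional_charge(sites$pKa[i], sites$polarity[i], pH), numeric(1))
}

# Nearest integer, ties away from zero (so +1.5 -> +2, -1.5 -> -2).
#' @keywords internal
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Fit the protonation model of a peptide
#'
#' Builds the per-site Henderson-Hasselbalch charge model: the set of
#' ionizable sites with their pKa values. The returned object supports
#' `predict()` (net or per-site charge at new pH values), `coef()` (site
#' pKa values), `summary()` (isoelectric point, mass, sites) and `plot()`
#' (titration curve).
#'
#' @param x A [peptide()] or sequence string.
#' @param pka A [pka_set()] or set name.
#' @return An object of class `protonation_model`.
#' @examples
#' m <- protonation_model(peptide("AAAAAAK"))
#' predict(m, pH = c(2, 7, 8, 11))
#' summary(m)
#' @export
protonation_model <- function(x, pka = pka_set("bjellqvist")) {
  p <- as_peptide(x)
  set <- pka_set(pka)
  sites <- ionizable_sites(p, set)
  structure(list(peptide = p, pka_set = set, sites = sites),
            class = "protonation_model")
}

#' @export
print.protonation_model <- function(x, ...) {
  print(x$peptide)
  cat(sprintf("Protonation model, pKa set '%s', %d ionizable site(s)\n",
              x$pka_set$name, nrow(x$sites)))
  if (nrow(x$sites)) print(x$sites, row.names = FALSE)
  invisible(x)
}

#' @export
coef.protonation_model <- function(object, ...) {
  s <- object$sites
  stats::setNames(s$pKa, paste0(s$site_kind, ifelse(
    s$site_kind == "side_chain", paste0(":", s$residue, s$residue_index), "")))
}

#' Predict charge at new pH values
#'
#' @param object A [protonation_model()].
#' @param pH Numeric vector of pH values in \[0, 14\].
#' @param type `"net"` for the summed net charge (numeric vector),
#'   `"sites"` for a matrix of per-site fractional charges (sites in
#'   columns).
#' @param ... Unused.
#' @return Net charge vector or per-site charge matrix, in e.
#' @export
predict.protonation_model <- function(object, pH,
                                      type = c("net", "sites"), ...) {
  type <- match.arg(type)
  if (any(!is.finite(pH)) || any(pH < 0) || any(pH > 14))
    stop("pH must lie in [0, 14]", call. = FALSE)
  if (nrow(object$sites) == 0L) {
    m <- matrix(numeric(0), nrow = length(pH), ncol = 0)
    return(if (type == "sites") m else rep(0, length(pH)))
  }
  m <- vapply(pH, function(h) site_charges_at(object$sites, h),
              numeric(nrow(object$sites)))
  m <- matrix(m, nrow = length(pH), byrow = TRUE,
              dimnames = list(NULL, names(coef(object))))
  if (type == "sites") m else rowSums(m)
}

#' @export
summary.protonation_model <- function(object, ...) {
  pI <- tryCatch(isoelectric_point(object, digits = NULL),
                 error = function(e) NA_real_)
  structure(list(model = object,
                 pI = pI,
                 mw = molecular_weight(object$peptide),
                 net7 = predict(object, 7)),
            class = "summary.protonation_model")
}

#' @export
print.summary.protonation_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("Average mass: %.2f g/mol\n", x$mw))
  cat(sprintf("Net charge at pH 7: %+.3f e\n", x$net7))
  if (is.na(x$pI)) cat("Isoelectric point: none (charge never crosses 0)\n")
  else cat(sprintf("Isoelectric point: %.2f\n", x$pI))
  invisible(x)
}

#' @export
plot.protonation_model <- function(x, from = 0, to = 14, n = 281, ...) {
  grid <- seq(from, to, length.out = n)
  q <- predict(x, grid)
  plot(grid, q, type = "l", xlab = "pH", ylab = "net charge (e)", ...)
  graphics::abline(h = 0, lty = 3)
  pI <- tryCatch(isoelectric_point(x, digits = NULL),
                 error = function(e) NA_real_)
  if (!is.na(pI)) graphics::abline(v = pI, lty = 3)
  invisible(x)
}

#' Net charge of a peptide at one or more pH values
#'
#' @param x A [peptide()], sequence string or [protonation_model()].
#' @param pH Numeric vector of pH values in \[0, 14\].
#' @param pka A [pka_set()] or set name (ignored when `x` is already a
#'   model).
#' @return A data.frame of titration points with columns `pH`,
#'   `net_charge` (e) and `rounded` (nearest integer, ties away from
#'   zero).
#' @examples
#' net_charge(peptide("AAAAAAK"), c(2, 7, 8, 11))
#' @export
net_charge <- function(x, pH, pka = pka_set("bjellqvist")) {
  m <- if (inherits(x, "protonation_model")) x else protonation_model(x, pka)
  q <- if (length(pH)) predict(m, pH) else numeric(0)
  data.frame(pH = as.numeric(pH), net_charge = q,
             rounded = round_half_away(q))
}

#' Titration curve over a pH grid
#'
#' Pointwise [net_charge()] over `pH_grid`, preserving the input order.
#' An empty grid yields an empty data.frame.
#'
#' @inheritParams net_charge
#' @param pH_grid Numeric vector of pH values in \[0, 14\].
#' @return Data.frame as [net_charge()].
#' @export
titration_curve <- function(x, pH_grid, pka = pka_set("bjellqvist")) {
  net_charge(x, pH_grid, pka)
}

#' Isoelectric point by bisection
#'
#' Root of the net-charge function on pH \[0, 14\], bisected until the
#' absolute net charge falls below `tol`. Requires at least one acid and
#' one base site, otherwise the net charge never changes sign and no
#' isoelectric point exists.
#'
#' @param x A [peptide()], sequence string or [protonation_model()].
#' @param pka A [pka_set()] or set name.
#' @param tol Tolerance on |net charge| at the root (default 1e-4).
#' @param digits Decimal places for the reported pI (default 1, matching
#'   the usual reporting convention); `NULL` for the full-precision root.
#' @return pH of zero net charge.
#' @examples
#' isoelectric_point(peptide("AAAAAAK"))   # 8.8
#' isoelectric_point(peptide("A"))         # 5.6: mean of the two pKa
#' @export
isoelectric_point <- function(x, pka = pka_set("bjellqvist"), tol = 1e-4,
                              digits = 1) {
  m <- if (inherits(x, "protonation_model")) x else protonation_model(x, pka)
  s <- m$sites
  if (!any(s$polarity == "acid") || !any(s$polarity == "base"))
    stop("no isoelectric point: peptide needs at least one acid and one base site",
         call. = FALSE)
  f <- function(h) predict(m, h)
  lo <- 0; hi <- 14
  if (f(lo) <= 0 || f(hi) >= 0)
    stop("no isoelectric point: net charge does not change sign on [0, 14]",
         call. = FALSE)
  repeat {
    mid <- (lo + hi) / 2
    q <- f(mid)
    if (abs(q) < tol || (hi - lo) < 1e-12) break
    if (q > 0) lo <- mid else hi <- mid
  }
  if (is.null(digits)) mid else round(mid, digits)
}

#' Per-site charge-state report at a pH
#'
#' Labels every ionizable site from the magnitude of its fractional
#' charge: `charged` (|q| >= 0.9), `mostly_charged` (\[0.7, 0.9)), `mixed`
#' ((0.3, 0.7)), `mostly_neutral` ((0.1, 0.3\]) and `neutral`
#' (|q| <= 0.1). The thresholds reproduce the usual verbal categories
#' ("substantially uncharged", "almost uncharged") and are configurable.
#'
#' @inheritParams net_charge
#' @param pH A single pH in \[0, 14\].
#' @param thresholds Increasing numeric vector of the four |q| cut points.
#' @return An object of class `charge_state`: list with `pH`, `sites`
#'   (data.frame with `charge` and `label` columns), `net_charge` and
#'   `rounded_net_charge`.
#' @examples
#' charge_state(peptide("AAAAAAK"), pH = 8)
#' @export
charge_state <- function(x, pH, pka = pka_set("bjellqvist"),
                         thresholds = c(0.1, 0.3, 0.7, 0.9)) {
  stopifnot(length(pH) == 1L, length(thresholds) == 4L,
            !is.unsorted(thresholds))
  m <- if (inherits(x, "protonation_model")) x else protonation_model(x, pka)
  q <- site_charges_at(m$sites, pH)
  a <- abs(q)
  label <- ifelse(a <= thresholds[1], "neutral",
           ifelse(a <= thresholds[2], "mostly_neutral",
           ifelse(a <  thresholds[3], "mixed",
           ifelse(a <  thresholds[4], "mostly_charged", "charged"))))
  sites <- cbind(m$sites, charge = q, label = label)
  net <- sum(q)
  structure(list(pH = pH, sites = sites, net_charge = net,
                 rounded_net_charge = round_half_away(net)),
            class = "charge_state")
}

#' @export
print.charge_state <- function(x, ...) {
  cat(sprintf("Charge state at pH %g: net %+.3f e (rounds to %+d e)\n",
              x$pH, x$net_charge, x$rounded_net_charge))
  print(x$sites[, c("site_kind", "residue", "residue_index", "pKa",
                    "charge", "label")], row.names = FALSE)
  invisible(x)
}
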
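#' Rate constants for the receptor gating scheme
#'
#' Bundles the elementary rate constants of the four-site AMPA-receptor
#' gating model together with the dimensionless binding-rate factor
#' \code{f}.  The defaults are the published wild-type set for GluA2:
#' channel opening \code{beta} = 5000 s^-1, closing \code{alpha} =
#' 3000 s^-1, per-site association \code{k_plus} = 5e6 M^-1 s^-1,
#' per-site dissociation \code{k_minus} = 1e4 s^-1, desensitization entry
#' from liganded closed states \code{d_plus} = 250 s^-1 and recovery
#' \code{d_minus} = 60 s^-1, and the unliganded desensitization pair
#' \code{d0_plus} = 1 s^-1, \code{d0_minus} = 9 s^-1.
#'
#' @param beta channel opening rate (s^-1).
#' @param alpha channel closing rate (s^-1).
#' @param k_plus per-site agonist association rate (M^-1 s^-1).
#' @param k_minus per-site agonist dissociation rate (s^-1).
#' @param d_plus desensitization entry rate from liganded closed states (s^-1).
#' @param d_minus desensitization recovery rate (s^-1).
#' @param d0_plus desensitization entry rate from the unliganded closed
#'   state (s^-1).
#' @param d0_minus recovery rate from the unliganded desensitized state (s^-1).
#' @param f dimensionless binding-rate factor applied to both \code{k_plus}
#'   and \code{k_minus}; models mutations that slow the binding pathway
#'   without changing affinity.
#' @return An object of class \code{rate_constants}.
#' @examples
#' rates <- rate_constants()
#' rates$k_plus
#' @export
rate_constants <- function(beta = 5000, alpha = 3000,
                           k_plus = 5e6, k_minus = 10000,
                           d_plus = 250, d_minus = 60,
                           d0_plus = 1, d0_minus = 9,
                           f = 1) {
  r <- list(beta = beta, alpha = alpha,
            k_plus = k_plus, k_minus = k_minus,
            d_plus = d_plus, d_minus = d_minus,
            d0_plus = d0_plus, d0_minus = d0_minus,
            f = f)
  validate_rates(r)
  structure(r, class = "rate_constants")
}

validate_rates <- function(r) {
  num <- vapply(r, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all rate constants must be finite scalars", call. = FALSE)
  rates <- unlist(r[setdiff(names(r), "f")])
  if (any(rates < 0))
    stop("rate constants must be non-negative: ",
         paste(names(rates)[rates < 0], collapse = ", "), call. = FALSE)
  if (r$f <= 0)
    stop("binding-rate factor f must be > 0", call. = FALSE)
  invisible(r)
}

#' Scale association and dissociation rates by a common factor
#'
#' Multiplies \code{k_plus} and \code{k_minus} by \code{f}, leaving every
#' other rate untouched.  Because both rates scale together the per-site
#' equilibrium constant \code{k_plus / k_minus} is invariant: the factor
#' slows (or speeds) traffic along the binding pathway without changing
#' agonist affinity, mimicking mutations that disrupt the approach route
#' to the binding pocket.
#'
#' @param rates a \code{\link{rate_constants}} object.
#' @param f positive scale factor.
#' @return A new \code{rate_constants} object with the scaled binding rates
#'   and \code{f} recorded.
#' @examples
#' scale_binding(rate_constants(), 0.5)$k_plus  # 2.5e6
#' @export
scale_binding <- function(rates, f) {
  stopifnot(inherits(rates, "rate_constants"))
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f) || f <= 0)
    stop("f must be a positive finite scalar", call. = FALSE)
  out <- unclass(rates)
  out$k_plus <- out$k_plus * f
  out$k_minus <- out$k_minus * f
  out$f <- rates$f * f
  structure(out, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Receptor gating rate constants:\n")
  for (nm in names(x))
    cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}
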
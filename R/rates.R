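# Force-dependent rate laws for bond and filament-end kinetics.

#' Force-dependent reaction rate
#'
#' Modifies a base (zero-load) rate by the tensile force magnitude carried
#' by the bond or filament tip:
#' \describe{
#'   \item{slip}{\code{base * exp(F / F_c)} — unbinding accelerates under
#'     load (alpha-actinin, characteristic force 17.2 pN).}
#'   \item{catch}{\code{base * exp(-F / F_c)} — unbinding slows under load
#'     (NMII ensemble, 12.6 pN per bound head).}
#'   \item{stall}{\code{base * max(0, 1 - F / F_c)} — linear stall of motor
#'     walking (15 pN per bound head).}
#'   \item{ratchet}{\code{base * exp(-F / F_c)} — Brownian-ratchet
#'     suppression of polymerization against a surface (1.5 pN).}
#'   \item{constant}{\code{base}.}
#' }
#' At zero force every law returns the base rate.
#'
#' @param base zero-load rate (per s, >= 0).
#' @param force tensile force magnitude (pN, >= 0); callers pass magnitudes.
#' @param law one of \code{"slip"}, \code{"catch"}, \code{"stall"},
#'   \code{"ratchet"}, \code{"constant"}.
#' @param f_char characteristic (or stall) force in pN; must be > 0 for all
#'   non-constant laws.
#' @return The modified rate (per s).
#' @examples
#' mechanochemical_rate(0.3, 17.2, "slip", 17.2)   # 0.3 * e
#' mechanochemical_rate(1, 15, "stall", 15)        # 0 at stall
#' @export
mechanochemical_rate <- function(base, force, law = c("slip", "catch",
                                                      "stall", "ratchet",
                                                      "constant"),
                                 f_char = NA_real_) {
  law <- match.arg(law)
  if (any(base < 0)) stop("base rate must be >= 0")
  if (any(force < 0)) stop("force must be a magnitude (>= 0)")
  if (law != "constant" && (!is.finite(f_char) || f_char <= 0))
    stop("characteristic force must be > 0 for law '", law, "'")
  switch(law,
    slip = base * exp(pmin(force / f_char, 700)),
    catch = base * exp(-force / f_char),
    stall = base * pmax(0, 1 - force / f_char),
    ratchet = base * exp(-force / f_char),
    constant = base)
}
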
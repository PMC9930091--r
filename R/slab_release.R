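# Fickian release from a plane gel slab.
#
# For a slab of diffusional thickness L_d releasing from both faces the
# exact cumulative fractional release is the classical series
#   Mt/Minf = 1 - sum_{n>=0} 8 / ((2n+1)^2 pi^2) exp(-(2n+1)^2 pi^2 D t / L_d^2)
# and its early-time limit is Mt/Minf = 4 sqrt(D t / (pi L_d^2)).
# A gel resting on the bottom of a tube releases only through its top face;
# by symmetry this equals one half of a slab of thickness 2L, so the
# one-sided geometry uses L_d = 2L with the same prefactor.

# Diffusional thickness for a geometry.
diffusional_thickness <- function(L, geometry = c("one_sided", "two_sided")) {
  geometry <- match.arg(geometry)
  if (geometry == "one_sided") 2 * L else L
}

#' Exact-series cumulative release from a plane slab
#'
#' Evaluates the exact Fourier-series solution for cumulative fractional
#' release `Mt/Minf` from a plane slab with uniform initial loading and a
#' perfect-sink boundary. The one-sided geometry (impermeable base, release
#' through the top face only, the in vitro tube configuration) is modelled
#' as half of a symmetric slab of thickness `2L`. This routine is the
#' brute-force oracle for the early-time approximation used in the release
#' kinetics.
#'
#' @param D Diffusion coefficient in m^2 s^-1 (> 0).
#' @param L Slab thickness in m (> 0).
#' @param times Times in seconds (>= 0).
#' @param one_sided If `TRUE` (default) release occurs through one face.
#' @param n_terms Number of series terms (default 200).
#' @return Cumulative fractional release in `[0, 1]`, non-decreasing in
#'   time, one value per element of `times`.
#' @export
simulate_slab_release <- function(D, L, times, one_sided = TRUE,
                                  n_terms = 200L) {
  if (!is.numeric(D) || D <= 0) abort("`D` must be positive.")
  if (!is.numeric(L) || L <= 0) abort("`L` must be positive.")
  if (any(times < 0)) abort("`times` must be non-negative.")
  if (n_terms < 1L) abort("`n_terms` must be at least 1.")
  Ld <- diffusional_thickness(L, if (one_sided) "one_sided" else "two_sided")
  n <- seq_len(n_terms) - 1L
  lam <- (2 * n + 1)^2 * pi^2 * D / Ld^2
  w <- 8 / ((2 * n + 1)^2 * pi^2)
  # the truncated tail (weight 1 - sum(w)) decays at least as fast as the
  # last retained term; folding it in keeps F(0) = 0 exactly
  w_tail <- 1 - sum(w)
  lam_tail <- lam[n_terms]
  frac <- vapply(times, function(t) {
    1 - sum(w * exp(-lam * t)) - w_tail * exp(-lam_tail * t)
  }, numeric(1))
  pmin(pmax(frac, 0), 1)
}

#' Early-time (square-root-of-time) slab release approximation
#'
#' `Mt/Minf = P sqrt(D t / (pi L_d^2))` with prefactor `P = 4` and
#' diffusional thickness `L_d = 2L` (one-sided) or `L` (two-sided). Valid
#' for roughly `Mt/Minf <= 0.6`; the release-rate regression and diffusion
#' coefficient inversion use this relation.
#'
#' @inheritParams simulate_slab_release
#' @param prefactor Geometric prefactor P (default 4).
#' @return Fractional release per time (not clipped; can exceed 1 outside
#'   the early-time regime).
#' @export
early_time_release <- function(D, L, times, one_sided = TRUE, prefactor = 4) {
  if (!is.numeric(D) || D <= 0) abort("`D` must be positive.")
  if (!is.numeric(L) || L <= 0) abort("`L` must be positive.")
  Ld <- diffusional_thickness(L, if (one_sided) "one_sided" else "two_sided")
  prefactor * sqrt(D * times / (pi * Ld^2))
}
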
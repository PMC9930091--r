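# Release kinetics: cumulative release from concentration/volume series,
# square-root-of-time rate constants, diffusion coefficients, mesh size,
# and the in vitro / in vivo comparison.

#' Cumulative release from a concentration and volume time series
#'
#' Converts mean gel concentration C(t) and gel volume V(t) into cumulative
#' release as a percentage of the dose present at the first time point t1:
#'
#' * volume-corrected: `100 (1 - C(t) V(t) / (C(t1) V(t1)))` — the agent
#'   mass remaining in the gel relative to its initial mass;
#' * apparent: the same with the volume held at `V(t1)`, i.e.
#'   `100 (1 - C(t)/C(t1))` — what a concentration-only readout would give
#'   when the gel swells or shrinks.
#'
#' Both are zero at t1 by construction.
#'
#' @param data Data frame with one row per MRI time point.
#' @param time,conc,volume Column names (tidy-eval) holding time (h), mean
#'   gel concentration (any fixed unit), and gel volume (any fixed unit).
#'   `volume` may be omitted, in which case only apparent release is
#'   computed and the corrected column equals it.
#' @return A `release_series` tibble: input columns plus
#'   `release_apparent_pct` and `release_corrected_pct`.
#' @export
cumulative_release <- function(data, time = time_h, conc = conc_mM,
                               volume = volume_uL) {
  d <- as_tibble(data)
  t <- dplyr::pull(d, {{ time }})
  C <- dplyr::pull(d, {{ conc }})
  has_vol <- tryCatch({
    V <- dplyr::pull(d, {{ volume }}); TRUE
  }, error = function(e) FALSE)
  if (!has_vol) V <- rep(1, length(C))

  if (length(t) < 2L) abort("At least two time points are required.")
  if (any(diff(t) <= 0)) abort("Time points must be strictly increasing.")
  if (is.na(C[1]) || C[1] <= 0)
    abort("Reference concentration C(t1) must be positive.")
  if (any(V <= 0, na.rm = TRUE)) abort("Volumes must be positive.")

  mass_ratio <- (C * V) / (C[1] * V[1])
  d$release_apparent_pct <- 100 * (1 - C / C[1])
  d$release_corrected_pct <- 100 * (1 - mass_ratio)
  class(d) <- c("release_series", class(d))
  d
}

# Resolve the release column used by downstream fits.
release_column <- function(series, release = c("corrected", "apparent")) {
  release <- match.arg(release)
  col <- paste0("release_", release, "_pct")
  if (!col %in% names(series))
    abort(sprintf("Series has no `%s` column; run cumulative_release().", col))
  col
}

#' Square-root-of-time release-rate regression
#'
#' Ordinary least squares of cumulative release (%) on the square root of
#' time (h), with a free intercept to absorb burst release. On
#' diffusion-controlled (Fickian) early-time data the relation is linear
#' and the slope is the release-rate constant k in % per h^(1/2).
#'
#' @param series A [cumulative_release()] result (or any data frame with a
#'   time column and a release column).
#' @param window Time window in hours, `c(min, max)`, inclusive; default
#'   the first 24 h.
#' @param release Which release to fit: `"corrected"` (default) or
#'   `"apparent"`.
#' @param time Tidy-eval column holding time in hours.
#' @return An object of class `rate_fit` with fields `k` (% h^-1/2),
#'   `intercept` (%), `r_squared`, `window`, the underlying `lm` fit and
#'   the fitted data.
#' @export
sqrt_time_fit <- function(series, window = c(0, 24),
                          release = c("corrected", "apparent"),
                          time = time_h) {
  d <- as_tibble(series)
  col <- release_column(d, release)
  t <- dplyr::pull(d, {{ time }})
  if (any(diff(t) <= 0)) abort("Time points must be strictly increasing.")
  if (length(window) != 2L || window[2] <= window[1])
    abort("`window` must be an increasing pair of hours.")
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 3L)
    abort("At least three time points are required inside the window.")
  dd <- tibble(sqrt_t = sqrt(t[keep]), release = d[[col]][keep])
  fit <- lm(release ~ sqrt_t, data = dd)
  structure(
    list(k = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = quiet_summary(fit)$r.squared, window = window,
         release = match.arg(release), fit = fit, data = dd),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> k = ", signif(x$k, 4), " % h^-1/2, intercept = ",
      signif(x$intercept, 4), " %, R^2 = ", signif(x$r_squared, 4),
      " (window ", x$window[1], "-", x$window[2], " h, ",
      x$release, " release)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rate_fit <- function(x, ...) {
  s <- quiet_summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "sqrt_time"),
    estimate = c(x$intercept, x$k),
    std_error = s[, 2],
    statistic = s[, 3],
    p_value = s[, 4]
  )
}

#' @exportS3Method generics::glance
glance.rate_fit <- function(x, ...) {
  tibble(k = x$k, intercept = x$intercept, r_squared = x$r_squared,
         window_min_h = x$window[1], window_max_h = x$window[2],
         release = x$release, n = nrow(x$data))
}

#' Compare release-rate constants between two series
#'
#' Pooled regression of release on sqrt(time) with a group interaction
#' term; the interaction coefficient is the slope difference and its F
#' statistic tests whether the two rate constants differ.
#'
#' @param a,b [cumulative_release()] series for the two groups.
#' @param labels Length-2 character labels for the groups.
#' @inheritParams sqrt_time_fit
#' @return A tibble with the two slopes, their difference, and the F test
#'   of the interaction (statistic, df, p value).
#' @export
compare_release_rates <- function(a, b, window = c(0, 24),
                                  release = c("corrected", "apparent"),
                                  labels = c("a", "b"), time = time_h) {
  release <- match.arg(release)
  fa <- sqrt_time_fit(a, window, release, {{ time }})
  fb <- sqrt_time_fit(b, window, release, {{ time }})
  pooled <- dplyr::bind_rows(
    dplyr::mutate(fa$data, group = labels[1]),
    dplyr::mutate(fb$data, group = labels[2])
  )
  full <- lm(release ~ sqrt_t * group, data = pooled)
  reduced <- lm(release ~ sqrt_t + group, data = pooled)
  an <- anova(reduced, full)
  tibble(
    group_a = labels[1], group_b = labels[2],
    k_a = fa$k, k_b = fb$k, k_diff = fa$k - fb$k,
    f_statistic = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
    p_value = an$`Pr(>F)`[2]
  )
}

#' Diffusion coefficient from a square-root-of-time rate constant
#'
#' Inverts the early-time slab relation
#' `Mt/Minf = P sqrt(D t / (pi L_d^2))`: with the slope per square-root
#' second `s = (k/100) / sqrt(3600)`, `D = pi L_d^2 s^2 / P^2`. The
#' diffusional thickness is `L_d = 2L` for one-sided release (gel slab on
#' the tube bottom releasing through its top face) and `L_d = L` for
#' two-sided release.
#'
#' @param k Release-rate constant in % per h^(1/2) (> 0), or a `rate_fit`.
#' @param L Gel slab thickness in m (> 0); the in vitro geometry has
#'   L = 5.5e-3 m.
#' @param geometry `"one_sided"` (default) or `"two_sided"`.
#' @param prefactor Geometric prefactor P (default 4).
#' @param D_water Optional free-solution diffusivity (m^2 s^-1) of the
#'   protein in water; when given, the hindrance factor `D_water / D` is
#'   reported.
#' @return A `diffusion_result` tibble with `D_m2_s`, `L_m`, `geometry`,
#'   `prefactor`, `k`, and `factor_vs_water` when `D_water` is supplied.
#' @export
diffusion_from_rate <- function(k, L, geometry = c("one_sided", "two_sided"),
                                prefactor = 4, D_water = NULL) {
  if (inherits(k, "rate_fit")) k <- k$k
  geometry <- match.arg(geometry)
  if (!is.numeric(k) || any(k <= 0)) abort("`k` must be positive.")
  if (!is.numeric(L) || any(L <= 0)) abort("`L` must be positive.")
  Ld <- diffusional_thickness(L, geometry)
  slope_s <- (k / 100) / sqrt(3600)
  D <- pi * Ld^2 * slope_s^2 / prefactor^2
  out <- tibble(D_m2_s = D, L_m = L, geometry = geometry,
                prefactor = prefactor, k = k)
  if (!is.null(D_water)) out$factor_vs_water <- D_water / D
  class(out) <- c("diffusion_result", class(out))
  out
}

#' Hydrogel mesh size from the storage modulus
#'
#' Rubber-elasticity estimate of the polymer-network mesh size:
#' `xi = (R T / (G' N_a))^(1/3)`, reported in nm (R = 8.314 J mol^-1 K^-1,
#' N_a = 6.022e23 mol^-1). Release is classified as diffusion-controlled
#' (`"diffusive"`) when the solute hydrodynamic diameter is smaller than
#' the mesh size, otherwise `"hindered"`. The default diameter is that of
#' albumin, 7.2 nm.
#'
#' @param G_prime Storage modulus in Pa (> 0); vectorised.
#' @param T Temperature in K (default 310.15, i.e. 37 C).
#' @param diameter_nm Solute hydrodynamic diameter in nm for the regime
#'   verdict.
#' @return A `mesh_result` tibble with `G_prime_pa`, `T_K`, `mesh_nm`,
#'   `diameter_nm` and `verdict`.
#' @export
mesh_size <- function(G_prime, T = 310.15, diameter_nm = 7.2) {
  if (!is.numeric(G_prime) || any(G_prime <= 0))
    abort("`G_prime` must be positive.")
  if (!is.numeric(T) || any(T <= 0)) abort("`T` must be positive.")
  xi_m <- (.GAS_CONSTANT * T / (G_prime * .AVOGADRO))^(1 / 3)
  xi_nm <- xi_m * 1e9
  out <- tibble(
    G_prime_pa = G_prime, T_K = T, mesh_nm = xi_nm,
    diameter_nm = diameter_nm,
    verdict = ifelse(diameter_nm < xi_nm, "diffusive", "hindered")
  )
  class(out) <- c("mesh_result", class(out))
  out
}

#' Plateau storage modulus from a rheology time sweep
#'
#' Mean G' over the final fraction of time points of a gelation time sweep,
#' the read-out fed into the mesh-size estimate.
#'
#' @param trace A data frame with columns `time_s` and `g_prime_pa`
#'   (e.g. from [generate_rheology_trace()]).
#' @param tail_fraction Fraction of the trace (by time points, from the
#'   end) to average over; in (0, 1], default 0.2.
#' @return A tibble with `g_plateau_pa`, `sd_pa` and `n_points`.
#' @export
estimate_plateau <- function(trace, tail_fraction = 0.2) {
  d <- as_tibble(trace)
  if (!all(c("time_s", "g_prime_pa") %in% names(d)))
    abort("`trace` needs columns `time_s` and `g_prime_pa`.")
  if (nrow(d) == 0L) abort("`trace` is empty.")
  if (tail_fraction <= 0 || tail_fraction > 1)
    abort("`tail_fraction` must be in (0, 1].")
  n <- max(1L, ceiling(tail_fraction * nrow(d)))
  g <- tail(d$g_prime_pa[order(d$time_s)], n)
  tibble(g_plateau_pa = mean(g),
         sd_pa = if (n > 1L) sd(g) else NA_real_,
         n_points = n)
}

#' In vitro / in vivo release comparison table
#'
#' Interpolates the volume-corrected release curves of an in vitro and an
#' in vivo series linearly in time at shared time points and tabulates the
#' paired differences and ratios.
#'
#' @param in_vitro,in_vivo [cumulative_release()] series.
#' @param times Time points (h) at which to compare; must lie within both
#'   observation spans (no extrapolation).
#' @param release `"corrected"` (default) or `"apparent"`.
#' @param time Tidy-eval time column.
#' @return An `ivivr_table` tibble: `time_h`, `in_vitro_pct`,
#'   `in_vivo_pct`, `difference_pp` (in vivo minus in vitro, percentage
#'   points) and `ratio`.
#' @export
ivivr_table <- function(in_vitro, in_vivo, times,
                        release = c("corrected", "apparent"),
                        time = time_h) {
  release <- match.arg(release)
  a <- as_tibble(in_vitro); b <- as_tibble(in_vivo)
  col_a <- release_column(a, release); col_b <- release_column(b, release)
  ta <- dplyr::pull(a, {{ time }}); tb <- dplyr::pull(b, {{ time }})
  lo <- max(min(ta), min(tb)); hi <- min(max(ta), max(tb))
  if (lo > hi) abort("Observation spans do not overlap.")
  if (any(times < lo) || any(times > hi))
    abort(sprintf("Requested times must lie within the shared span [%g, %g] h.",
                  lo, hi))
  va <- approx(ta, a[[col_a]], xout = times)$y
  vb <- approx(tb, b[[col_b]], xout = times)$y
  out <- tibble(time_h = times, in_vitro_pct = va, in_vivo_pct = vb,
                difference_pp = vb - va, ratio = vb / va)
  class(out) <- c("ivivr_table", class(out))
  out
}
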
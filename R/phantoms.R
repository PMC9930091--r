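# Synthetic phantoms with fully known ground truth.
#
# Tube phantoms emulate the in vitro configuration: a gel slab (40 uL,
# thickness L = 5.5 mm) on the bottom of a tube under a PBS supernatant
# (160 uL), releasing agent through its top face according to the exact
# Fickian slab solution, with the supernatant optionally refreshed between
# sessions. Brain-slice phantoms emulate the in vivo configuration: an
# ellipsoidal gel deposit in tissue whose volume follows a prescribed
# trajectory, with optional short-T1 rim and long-T1 peri-gel bands.
# Both render Look-Locker magnitude series through the same forward model
# the fitter uses, so a noiseless phantom round-trips exactly.

#' Specify a synthetic phantom
#'
#' Collects the geometry, ground-truth tissue/relaxometry parameters,
#' release physics, acquisition protocol and noise model for
#' [generate_tube_phantom()] or [generate_brain_phantom()]. Defaults
#' describe the study conditions: a 40 uL gel slab of thickness 5.5 mm
#' under 160 uL supernatant (tube), or a ~5.3 uL ellipsoidal deposit in
#' tissue (brain), imaged with a Look-Locker readout of 100 inversion
#' times starting at 10 ms spaced by TR_img = 25 ms at flip angle 5 deg.
#'
#' @param geometry `"tube"` or `"brain"`.
#' @param dim Grid dimensions in voxels (length 3). Defaults:
#'   `c(12, 12, 40)` (tube), `c(28, 24, 12)` (brain).
#' @param voxel_mm Voxel size in mm (length 3). Defaults:
#'   `c(0.4, 0.4, 0.5)` (tube), `c(0.2, 0.2, 0.5)` (brain).
#' @param L_mm Gel slab thickness in mm (diffusional geometry), default 5.5.
#' @param gel_uL Initial gel volume in uL (default 40 tube, 5.3 brain).
#' @param supernatant_uL Nominal supernatant volume in uL (tube; default
#'   160). Restored to this value at each refresh.
#' @param t1_gel_s,t1_medium_s,t1_background_s True T1 (s) of blank gel,
#'   supernatant (tube) or tissue (brain), and background.
#' @param r1_true True longitudinal relaxivity in mM^-1 s^-1, applied in
#'   gel and supernatant alike.
#' @param C0_mM Initial agent concentration in the gel (mM); default the
#'   0.75 mg/mL loading at 74 kDa.
#' @param D_true Diffusion coefficient of the agent in the gel, m^2 s^-1.
#' @param times_h Acquisition time points in hours (one image series each).
#' @param volume_uL Gel volume trajectory V(t) in uL, one value per time
#'   point (default: constant `gel_uL`).
#' @param refresh_h Times (h) at which the supernatant is replaced by
#'   fresh medium (concentration zeroed, volume restored).
#' @param sigma Noise standard deviation as a fraction of the
#'   proton-density signal (M0 = 1 inside the sample).
#' @param noise `"rician"` (magnitude MRI default) or `"gaussian"`.
#' @param ti_s Inversion times (s), strictly increasing.
#' @param tr_img_s Image repetition time of the readout train (s).
#' @param flip_deg Readout flip angle (deg).
#' @param seed RNG seed; identical specs and seeds give bit-identical
#'   phantoms.
#' @param gel_semiaxes_mm Brain geometry: ellipsoid semi-axes in mm used as
#'   the shape template (scaled to match `volume_uL`).
#' @param rim_width_vox,rim_t1_factor Optional short-T1 rim band around the
#'   gel (width in voxels; multiplicative factor on tissue T1, < 1).
#' @param edema_width_vox,edema_t1_factor Optional long-T1 peri-gel band
#'   beyond the rim (factor > 1).
#' @param release_fraction Optional prescribed cumulative release fraction
#'   per time point, overriding the Fickian slab model.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(geometry = c("tube", "brain"),
                         dim = NULL, voxel_mm = NULL,
                         L_mm = 5.5, gel_uL = NULL, supernatant_uL = 160,
                         t1_gel_s = 2.5, t1_medium_s = NULL,
                         t1_background_s = 1.0,
                         r1_true = 93.2, C0_mM = 0.75 / 74,
                         D_true = 7e-11,
                         times_h = c(1.5, 3, 6, 12, 24),
                         volume_uL = NULL, refresh_h = numeric(0),
                         sigma = 0, noise = c("rician", "gaussian"),
                         ti_s = 0.010 + 0.025 * (0:99),
                         tr_img_s = 0.025, flip_deg = 5, seed = 1L,
                         gel_semiaxes_mm = c(1.1, 1.1, 1.3),
                         rim_width_vox = 0L, rim_t1_factor = 0.8,
                         edema_width_vox = 0L, edema_t1_factor = 1.3,
                         release_fraction = NULL) {
  geometry <- match.arg(geometry)
  noise <- match.arg(noise)
  if (is.null(dim))
    dim <- if (geometry == "tube") c(12L, 12L, 40L) else c(28L, 24L, 12L)
  if (is.null(voxel_mm))
    voxel_mm <- if (geometry == "tube") c(0.4, 0.4, 0.5) else c(0.2, 0.2, 0.5)
  if (is.null(gel_uL)) gel_uL <- if (geometry == "tube") 40 else 5.3
  if (is.null(t1_medium_s))
    t1_medium_s <- if (geometry == "tube") 3.5 else 1.5
  if (is.null(volume_uL)) volume_uL <- rep(gel_uL, length(times_h))

  if (L_mm <= 0) abort("`L_mm` must be positive.")
  if (any(c(t1_gel_s, t1_medium_s, t1_background_s) <= 0))
    abort("All T1 values must be positive.")
  if (r1_true <= 0) abort("`r1_true` must be positive.")
  if (C0_mM < 0) abort("`C0_mM` must be non-negative.")
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (any(diff(ti_s) <= 0)) abort("Inversion times must be strictly increasing.")
  if (length(ti_s) < 4L) abort("At least 4 inversion times are required.")
  if (any(volume_uL <= 0)) abort("Volume trajectory must be positive.")
  if (length(volume_uL) != length(times_h))
    abort("`volume_uL` must have one value per time point.")
  if (length(times_h) >= 2L && any(diff(times_h) <= 0))
    abort("`times_h` must be strictly increasing.")
  if (!is.null(release_fraction)) {
    if (length(release_fraction) != length(times_h))
      abort("`release_fraction` must have one value per time point.")
    if (any(release_fraction < 0 | release_fraction > 1) ||
        any(diff(release_fraction) < 0))
      abort("`release_fraction` must be non-decreasing in [0, 1].")
  }

  structure(
    list(geometry = geometry, dim = as.integer(dim),
         voxel_mm = as.numeric(voxel_mm), L_mm = L_mm, gel_uL = gel_uL,
         supernatant_uL = supernatant_uL, t1_gel_s = t1_gel_s,
         t1_medium_s = t1_medium_s, t1_background_s = t1_background_s,
         r1_true = r1_true, C0_mM = C0_mM, D_true = D_true,
         times_h = times_h, volume_uL = volume_uL, refresh_h = refresh_h,
         sigma = sigma, noise = noise, ti_s = ti_s, tr_img_s = tr_img_s,
         flip_deg = flip_deg, seed = as.integer(seed),
         gel_semiaxes_mm = gel_semiaxes_mm,
         rim_width_vox = as.integer(rim_width_vox),
         rim_t1_factor = rim_t1_factor,
         edema_width_vox = as.integer(edema_width_vox),
         edema_t1_factor = edema_t1_factor,
         release_fraction = release_fraction),
    class = "phantom_spec"
  )
}

# Cumulative fractional release at the spec's time points.
spec_release_fraction <- function(spec) {
  if (!is.null(spec$release_fraction)) return(spec$release_fraction)
  simulate_slab_release(spec$D_true, spec$L_mm * 1e-3,
                        spec$times_h * 3600, one_sided = TRUE)
}

# T1 field -> Look-Locker magnitude image (noiseless), vectorised over the
# handful of unique T1 values a phantom contains.
render_ll_signal <- function(t1_field, m0_field, ti, tr_img, flip_deg) {
  d <- dim(t1_field)
  nt <- length(ti)
  sig <- array(0, dim = c(d, nt))
  live <- which(m0_field > 0)
  if (length(live) == 0L) return(sig)
  key <- paste(t1_field[live], m0_field[live])
  for (k in unique(key)) {
    vox <- live[key == k]
    t1 <- t1_field[vox[1]]; m0 <- m0_field[vox[1]]
    t1s <- t1_star_from_t1(t1, flip_deg, tr_img)
    A <- m0 * t1s / t1
    s <- forward_look_locker(A, A + m0, t1s, ti)
    for (j in seq_len(nt)) sig[vox + (j - 1L) * prod(d)] <- s[j]
  }
  sig
}

# Add magnitude noise in place (sigma in M0 units); consumes the RNG stream.
add_noise <- function(sig, sigma, model) {
  if (sigma <= 0) return(sig)
  n <- length(sig)
  if (model == "rician") {
    e1 <- rnorm(n, 0, sigma); e2 <- rnorm(n, 0, sigma)
    array(sqrt((sig + e1)^2 + e2^2), dim = dim(sig))
  } else {
    array(pmax(sig + rnorm(n, 0, sigma), 0), dim = dim(sig))
  }
}

# Tube interior: disc of the radius that gives area = gel_uL / L for the
# nominal slab, extended over all slices.
tube_mask_3d <- function(spec) {
  d <- spec$dim; v <- spec$voxel_mm
  area_mm2 <- spec$gel_uL / spec$L_mm
  r_mm <- sqrt(area_mm2 / pi)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  xy <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  disc <- ((xy$i - cx) * v[1])^2 + ((xy$j - cy) * v[2])^2 <= r_mm^2
  array(rep(disc, d[3]), dim = d)
}

# Bottom-up fill order of tube voxels (z-major, then radial), used to render
# gel volumes: the first n voxels in this order form a slab of volume
# n * voxel volume, nested across time points.
tube_fill_order <- function(tube, voxel_mm) {
  d <- dim(tube)
  idx <- which(tube)
  co <- arrayInd(idx, d)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  r2 <- ((co[, 1] - cx) * voxel_mm[1])^2 + ((co[, 2] - cy) * voxel_mm[2])^2
  idx[order(co[, 3], r2, idx)]
}

#' Generate a tube phantom series with known truth
#'
#' Renders one Look-Locker magnitude series per requested time point for a
#' gel slab under supernatant. The gel's agent mass follows the exact
#' Fickian slab solution (one-sided, thickness `L_mm`); the gel
#' concentration is mass over the prescribed volume `V(t)`; released mass
#' accumulates in the supernatant and is removed at refresh events
#' (concentration zeroed, volume restored). Voxel T1 follows
#' `1/T1 = 1/T1_blank + r1 C`; the magnitude signal uses the same forward
#' model as the fitter; noise is drawn from the spec's model under the
#' spec's seed, so identical specs give bit-identical output.
#'
#' @param spec A [phantom_spec()] with `geometry = "tube"`.
#' @return A `phantom_set`: list with `series` (list of [ir_series()], one
#'   per time point, masked to the tube interior) and `truth`
#'   (`phantom_truth`: per-time-point T1 and concentration fields, gel and
#'   supernatant masks, and a `release` tibble with time, gel volume, gel
#'   and supernatant concentrations and the true cumulative release
#'   fraction relative to the first time point).
#' @export
generate_tube_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$geometry != "tube") abort("`spec` must have tube geometry.")
  d <- spec$dim
  vv <- prod(spec$voxel_mm)           # uL per voxel
  tube <- tube_mask_3d(spec)
  fill <- tube_fill_order(tube, spec$voxel_mm)
  n_target <- round(spec$volume_uL / vv)
  if (any(n_target > length(fill)))
    abort("Volume trajectory exceeds the tube capacity.")
  if (any(n_target < 1L)) abort("Volume trajectory below one voxel.")

  tp <- length(spec$times_h)
  frac <- spec_release_fraction(spec)
  m0 <- spec$C0_mM * spec$volume_uL[1]          # mM * uL, conserved
  m_gel <- m0 * (1 - frac)
  C_gel <- m_gel / spec$volume_uL
  # supernatant: mass released since the last refresh before each scan
  last_refresh <- vapply(spec$times_h, function(t) {
    r <- spec$refresh_h[spec$refresh_h <= t]
    if (length(r)) max(r) else 0
  }, numeric(1))
  frac_at <- function(t) {
    if (!is.null(spec$release_fraction))
      approx(c(0, spec$times_h), c(0, spec$release_fraction), xout = t,
             rule = 2)$y
    else
      simulate_slab_release(spec$D_true, spec$L_mm * 1e-3, t * 3600)
  }
  C_sup <- m0 * (frac - frac_at(last_refresh)) / spec$supernatant_uL

  set.seed(spec$seed)
  series <- vector("list", tp)
  t1_fields <- vector("list", tp)
  conc_fields <- vector("list", tp)
  gel_masks <- vector("list", tp)
  sup_masks <- vector("list", tp)
  for (i in seq_len(tp)) {
    gel <- array(FALSE, dim = d)
    gel[fill[seq_len(n_target[i])]] <- TRUE
    sup <- tube & !gel
    conc <- array(0, dim = d)
    conc[gel] <- C_gel[i]; conc[sup] <- C_sup[i]
    t1 <- array(spec$t1_background_s, dim = d)
    t1[gel] <- 1 / (1 / spec$t1_gel_s + spec$r1_true * C_gel[i])
    t1[sup] <- 1 / (1 / spec$t1_medium_s + spec$r1_true * C_sup[i])
    m0_field <- array(0, dim = d); m0_field[tube] <- 1
    sig <- render_ll_signal(t1, m0_field, spec$ti_s, spec$tr_img_s,
                            spec$flip_deg)
    sig <- add_noise(sig, spec$sigma, spec$noise)
    series[[i]] <- ir_series(sig, spec$ti_s, spec$tr_img_s, spec$flip_deg,
                             spec$voxel_mm, mask = tube)
    t1_fields[[i]] <- t1; conc_fields[[i]] <- conc
    gel_masks[[i]] <- gel; sup_masks[[i]] <- sup
  }

  release <- tibble(
    time_h = spec$times_h,
    volume_uL = n_target * vv,
    conc_gel_mM = C_gel,
    conc_sup_mM = C_sup,
    fraction_released = 1 - m_gel / m_gel[1],
    fraction_released_total = frac
  )
  new_phantom_set(spec, series, t1_fields, conc_fields, gel_masks,
                  sup_masks, release)
}

# Continuous ellipsoid "radius" field used to carve nested gel masks.
ellipsoid_metric <- function(dim, voxel_mm, center_vox, semiaxes_mm) {
  g <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                   k = seq_len(dim[3]))
  m <- sqrt(((g$i - center_vox[1]) * voxel_mm[1] / semiaxes_mm[1])^2 +
            ((g$j - center_vox[2]) * voxel_mm[2] / semiaxes_mm[2])^2 +
            ((g$k - center_vox[3]) * voxel_mm[3] / semiaxes_mm[3])^2)
  array(m, dim = dim)
}

#' Generate a brain-slice phantom series with known truth
#'
#' Renders a multi-slice Look-Locker series of an ellipsoidal gel deposit
#' in tissue. The gel volume follows `V(t)` by thresholding a continuous
#' ellipsoidal radius field at the level containing the target voxel count,
#' so masks stay nested and shape-preserving as the gel swells or shrinks.
#' Optional short-T1 rim and long-T1 peri-gel (edema-like) bands surround
#' the gel. Agent concentration in the gel evolves as in the tube phantom;
#' released agent is taken as cleared from the imaged slice (tissue
#' concentration 0).
#'
#' @param spec A [phantom_spec()] with `geometry = "brain"`.
#' @return A `phantom_set` as for [generate_tube_phantom()] (the
#'   supernatant masks are `NULL`).
#' @export
generate_brain_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$geometry != "brain") abort("`spec` must have brain geometry.")
  d <- spec$dim
  vv <- prod(spec$voxel_mm)
  center <- c((d[1] + 1) / 2 + d[1] / 4, (d[2] + 1) / 2, (d[3] + 1) / 2)
  metric <- ellipsoid_metric(d, spec$voxel_mm, center, spec$gel_semiaxes_mm)
  ord <- order(metric, seq_along(metric))
  n_target <- round(spec$volume_uL / vv)
  if (any(n_target < 1L)) abort("Volume trajectory below one voxel.")
  if (any(n_target > prod(d)))
    abort("Gel ellipsoid is not fully inside the grid.")

  tp <- length(spec$times_h)
  frac <- spec_release_fraction(spec)
  m0 <- spec$C0_mM * spec$volume_uL[1]
  m_gel <- m0 * (1 - frac)
  C_gel <- m_gel / spec$volume_uL

  border <- array(TRUE, dim = d)
  border[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE

  set.seed(spec$seed)
  series <- vector("list", tp)
  t1_fields <- vector("list", tp)
  conc_fields <- vector("list", tp)
  gel_masks <- vector("list", tp)
  for (i in seq_len(tp)) {
    gel <- array(FALSE, dim = d)
    gel[ord[seq_len(n_target[i])]] <- TRUE
    if (any(gel & border))
      abort("Gel ellipsoid is not fully inside the grid.")
    t1 <- array(spec$t1_medium_s, dim = d)
    if (spec$rim_width_vox > 0L) {
      rim <- mask_dilate(gel, spec$rim_width_vox) & !gel
      t1[rim] <- spec$t1_medium_s * spec$rim_t1_factor
    }
    if (spec$edema_width_vox > 0L) {
      inner <- mask_dilate(gel, spec$rim_width_vox)
      edema <- mask_dilate(inner, spec$edema_width_vox) & !inner
      t1[edema] <- spec$t1_medium_s * spec$edema_t1_factor
    }
    conc <- array(0, dim = d); conc[gel] <- C_gel[i]
    t1[gel] <- 1 / (1 / spec$t1_gel_s + spec$r1_true * C_gel[i])
    m0_field <- array(1, dim = d)
    sig <- render_ll_signal(t1, m0_field, spec$ti_s, spec$tr_img_s,
                            spec$flip_deg)
    sig <- add_noise(sig, spec$sigma, spec$noise)
    series[[i]] <- ir_series(sig, spec$ti_s, spec$tr_img_s, spec$flip_deg,
                             spec$voxel_mm)
    t1_fields[[i]] <- t1; conc_fields[[i]] <- conc; gel_masks[[i]] <- gel
  }

  release <- tibble(
    time_h = spec$times_h,
    volume_uL = n_target * vv,
    conc_gel_mM = C_gel,
    conc_sup_mM = NA_real_,
    fraction_released = 1 - m_gel / m_gel[1],
    fraction_released_total = frac
  )
  new_phantom_set(spec, series, t1_fields, conc_fields, gel_masks,
                  NULL, release)
}

new_phantom_set <- function(spec, series, t1_fields, conc_fields,
                            gel_masks, sup_masks, release) {
  truth <- structure(
    list(t1_fields = t1_fields, conc_fields = conc_fields,
         gel_masks = gel_masks, sup_masks = sup_masks,
         release = release, seed = spec$seed),
    class = "phantom_truth"
  )
  structure(list(spec = spec, series = series, truth = truth),
            class = "phantom_set")
}

#' @export
print.phantom_set <- function(x, ...) {
  cat("<phantom_set> ", x$spec$geometry, " geometry, ",
      length(x$series), " time points, grid ",
      paste(x$spec$dim, collapse = " x "), ", sigma = ", x$spec$sigma,
      " (", x$spec$noise, "), seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Synthetic gelation rheology time sweep
#'
#' Saturating-exponential storage-modulus build-up
#' `G'(t) = G_inf (1 - exp(-t/tau))` with optional additive Gaussian
#' noise, emulating an in situ gelation time sweep. A loss modulus is
#' included as a fixed fraction of G'.
#'
#' @param G_inf Plateau storage modulus in Pa (> 0).
#' @param tau Build-up time constant in seconds (> 0).
#' @param times Times in seconds.
#' @param noise_sd Additive noise SD in Pa.
#' @param seed RNG seed.
#' @param loss_ratio G''/G' ratio (default 0.11).
#' @return A `rheology_trace` tibble with `time_s`, `g_prime_pa`,
#'   `g_double_prime_pa`.
#' @export
generate_rheology_trace <- function(G_inf, tau, times, noise_sd = 0,
                                    seed = 1L, loss_ratio = 0.11) {
  if (!is.numeric(G_inf) || G_inf <= 0) abort("`G_inf` must be positive.")
  if (!is.numeric(tau) || tau <= 0) abort("`tau` must be positive.")
  set.seed(seed)
  g <- G_inf * (1 - exp(-times / tau))
  if (noise_sd > 0) g <- g + rnorm(length(times), 0, noise_sd)
  out <- tibble(time_s = as.numeric(times), g_prime_pa = g,
                g_double_prime_pa = loss_ratio * g)
  class(out) <- c("rheology_trace", class(out))
  out
}
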
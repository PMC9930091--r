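# Look-Locker inversion-recovery modelling and voxel-wise T1 fitting.
#
# After a single inversion pulse the longitudinal magnetisation is sampled
# repeatedly with small-flip-angle readouts every TR_img, so it relaxes with
# an effective time constant T1* toward a reduced steady state M0*:
#   1/T1* = 1/T1 - ln(cos(alpha)) / TR_img
#   M0*   = M0 * T1* / T1
# The magnitude signal is |A - B exp(-t/T1*)| with A = M0* and B = M0 + M0*,
# and the true T1 is recovered from the fit as T1 = T1* (B/A - 1).

#' Look-Locker magnitude signal model
#'
#' Evaluates `|A - B exp(-t/T1*)|` at the requested inversion times. Used
#' both as the fitting model and as the forward model in the phantom
#' generator.
#'
#' @param A Steady-state amplitude M0* (signal units, > 0 for physical
#'   signals).
#' @param B Recovery amplitude M0 + M0* (signal units).
#' @param t1_star Effective relaxation time T1* in seconds (> 0).
#' @param times Inversion times in seconds.
#' @return Numeric vector of magnitudes, one per inversion time.
#' @export
forward_look_locker <- function(A, B, t1_star, times) {
  if (!is.numeric(t1_star) || t1_star <= 0)
    abort("`t1_star` must be positive.")
  abs(A - B * exp(-times / t1_star))
}

# Effective T1* for a given true T1 under the readout train.
t1_star_from_t1 <- function(t1, flip_deg, tr_img) {
  1 / (1 / t1 - log(cos(flip_deg * pi / 180)) / tr_img)
}

#' Construct an inversion-recovery image series
#'
#' Bundles a magnitude image stack with its inversion-time axis and
#' acquisition metadata. The stack may be a matrix (voxels x inversion
#' times) or a 4D array (x, y, z, inversion time).
#'
#' @param data Numeric matrix (voxels x times) or 4D array, magnitudes >= 0.
#' @param ti Inversion times in seconds, strictly increasing, length >= 4.
#' @param tr_img Image repetition time of the readout train in seconds.
#' @param flip_deg Readout flip angle in degrees.
#' @param voxel_mm Voxel dimensions in mm (length 3), used for volumetry.
#' @param mask Optional logical analysis mask (3D array matching the image
#'   grid, or vector for matrix input).
#' @return An object of class `ir_series`.
#' @export
ir_series <- function(data, ti, tr_img, flip_deg, voxel_mm = c(1, 1, 1),
                      mask = NULL) {
  if (length(ti) < 4L)
    abort("At least 4 inversion times are required (3 parameters + 1 d.o.f.).")
  if (any(diff(ti) <= 0))
    abort("Inversion times must be strictly increasing.")
  if (any(data < 0)) abort("Magnitude data must be non-negative.")
  nd <- length(dim(data))
  if (!nd %in% c(2L, 4L))
    abort("`data` must be a voxels-x-times matrix or a 4D array.")
  nt <- if (nd == 2L) ncol(data) else dim(data)[4]
  if (nt != length(ti))
    abort("Last data dimension must match the number of inversion times.")
  structure(
    list(data = data, ti = as.numeric(ti), tr_img = tr_img,
         flip_deg = flip_deg, voxel_mm = rep_len(as.numeric(voxel_mm), 3L),
         mask = mask),
    class = "ir_series"
  )
}

#' @export
print.ir_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<ir_series> ",
      if (length(d) == 4L) paste(d[1:3], collapse = " x ") else paste(d[1], "voxels"),
      ", ", length(x$ti), " inversion times (",
      signif(min(x$ti), 3), "-", signif(max(x$ti), 3), " s), TR_img ",
      x$tr_img * 1000, " ms, flip ", x$flip_deg, " deg\n", sep = "")
  invisible(x)
}

# Signal matrix (voxels x times) and grid bookkeeping for a series.
series_signal_matrix <- function(series) {
  d <- dim(series$data)
  if (length(d) == 2L) {
    list(signals = series$data, grid = NULL,
         mask = series$mask %||% rep(TRUE, d[1]))
  } else {
    m <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
    msk <- series$mask %||% array(TRUE, dim = d[1:3])
    list(signals = m, grid = d[1:3], mask = as.vector(msk))
  }
}

# Fit one voxel's magnitude recovery. Polarity of the pre-nulling samples is
# restored by trying sign-flip cut points around the magnitude minimum and
# keeping the flip with the smallest residual sum of squares.
fit_voxel_ll <- function(y, t, t1_lower = 1e-3, t1_upper = 20) {
  out <- c(A = NA_real_, B = NA_real_, t1_star = NA_real_, rss = NA_real_,
           rel_residual = NA_real_, converged = 0)
  if (all(y == 0) || sd(y) == 0) return(out)

  n <- length(y)
  n_tail <- max(1L, round(0.1 * n))
  A0 <- mean(y[(n - n_tail + 1L):n])
  if (A0 <= 0) A0 <- max(mean(y), 1e-6)
  B0 <- A0 + max(y)
  jmin <- which.min(y)
  t1s0 <- min(max(t[jmin] / log(2), t1_lower * 2), t1_upper / 2)
  cuts <- unique(pmax(0L, pmin(n, c(0L, jmin - 2L, jmin - 1L, jmin, jmin + 1L))))

  best <- NULL
  for (j in cuts) {
    s <- y
    if (j > 0L) s[1:j] <- -s[1:j]
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = list(A = A0, B = B0, t1s = t1s0),
        lower = c(1e-12, 1e-12, t1_lower), upper = c(Inf, Inf, t1_upper),
        fn = function(p) s - (p$A - p$B * exp(-t / p$t1s)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(out)

  p <- best$fit$par
  rel_res <- sqrt(best$rss / n) / p$A
  # info 4 (gradient orthogonal to residual) at a negligible residual is an
  # exact fit, reached on noiseless data
  conv <- best$fit$info %in% 1:3 || (best$fit$info == 4 && rel_res < 1e-6)
  c(A = p$A, B = p$B, t1_star = p$t1s, rss = best$rss,
    rel_residual = rel_res, converged = as.numeric(conv))
}

#' Voxel-wise three-parameter Look-Locker fit
#'
#' Fits `|A - B exp(-t/T1*)|` to every voxel in the analysis mask by
#' nonlinear least squares (Levenberg-Marquardt), with magnitude-polarity
#' restoration: candidate zero-crossing cut points around the magnitude
#' minimum are tried, the pre-crossing samples sign-flipped, and the flip
#' with the lowest residual kept. Identical voxel time courses are fitted
#' once and the result reused, which makes noiseless phantom fits fast.
#'
#' Voxels are accepted when the fit converged, `A > 0`, `B > A`,
#' `T1* > 0` and the relative residual (RMS residual / A) is below
#' `max_rel_residual`; all-zero voxels are flagged, not errors.
#'
#' @param series An [ir_series()].
#' @param max_rel_residual Acceptance threshold on RMS residual / A
#'   (default 0.2).
#' @param t1_star_bounds Lower/upper bounds on T1* in seconds
#'   (default 1 ms to 20 s, covering tissue, gel and PBS).
#' @return An object of class `look_locker_fit`: a tibble with one row per
#'   masked voxel (`voxel`, grid coordinates for 4D input, `A`, `B`,
#'   `t1_star`, `rss`, `rel_residual`, `converged`, `accepted`), carrying
#'   the acquisition metadata as attributes.
#' @export
fit_look_locker <- function(series, max_rel_residual = 0.2,
                            t1_star_bounds = c(1e-3, 20)) {
  stopifnot(inherits(series, "ir_series"))
  sm <- series_signal_matrix(series)
  idx <- which(sm$mask)
  if (length(idx) == 0L) abort("Analysis mask is empty.")
  sig <- sm$signals[idx, , drop = FALSE]

  # fit unique time courses only
  keys <- apply(sig, 1L, paste, collapse = "\r")
  first <- !duplicated(keys)
  map <- match(keys, keys[first])
  ufit <- t(vapply(
    which(first),
    function(i) fit_voxel_ll(sig[i, ], series$ti,
                             t1_star_bounds[1], t1_star_bounds[2]),
    numeric(6)
  ))
  res <- ufit[map, , drop = FALSE]

  out <- as_tibble(res)
  out$converged <- out$converged > 0
  out$voxel <- idx
  out$accepted <- out$converged &
    !is.na(out$A) & out$A > 0 & out$B > out$A & out$t1_star > 0 &
    out$rel_residual <= max_rel_residual
  if (!is.null(sm$grid)) {
    co <- arrayInd(idx, sm$grid)
    out$x <- co[, 1]; out$y <- co[, 2]; out$z <- co[, 3]
  }
  out <- out[, c("voxel", intersect(c("x", "y", "z"), names(out)),
                 "A", "B", "t1_star", "rss", "rel_residual",
                 "converged", "accepted")]
  structure(out,
            grid = sm$grid, ti = series$ti, tr_img = series$tr_img,
            flip_deg = series$flip_deg, voxel_mm = series$voxel_mm,
            class = c("look_locker_fit", class(out)))
}

#' Correct Look-Locker parameters to true T1
#'
#' Applies the readout-train correction `T1 = T1* (B/A - 1)` to the
#' accepted voxels of a Look-Locker fit and returns a relaxation map with
#' both T1 and R1 = 1/T1. Accepted voxels in which `B <= A` (a
#' non-physical recovery) are dropped from the mask and counted.
#'
#' @param fit A [fit_look_locker()] result.
#' @return An object of class `relaxation_map`: a list with 3D arrays `t1`
#'   (s) and `r1` (s^-1), a logical `mask` of accepted voxels, the dropped
#'   voxel count, voxel dimensions, and the per-voxel tibble `values`. For
#'   matrix-input fits the arrays are vectors.
#' @export
correct_t1 <- function(fit) {
  stopifnot(inherits(fit, "look_locker_fit"))
  v <- as_tibble(fit)
  ok <- v$accepted
  bad_ba <- ok & v$B <= v$A
  ok <- ok & !bad_ba
  t1 <- ifelse(ok, v$t1_star * (v$B / v$A - 1), NA_real_)
  v$t1 <- t1
  v$r1 <- 1 / t1

  grid <- attr(fit, "grid")
  if (is.null(grid)) {
    t1_arr <- t1
    mask_arr <- ok
  } else {
    t1_arr <- array(NA_real_, dim = grid)
    mask_arr <- array(FALSE, dim = grid)
    t1_arr[v$voxel] <- t1
    mask_arr[v$voxel] <- ok
  }
  structure(
    list(t1 = t1_arr, r1 = 1 / t1_arr, mask = mask_arr,
         n_dropped_b_le_a = sum(bad_ba), voxel_mm = attr(fit, "voxel_mm"),
         values = v[ok, c("voxel", intersect(c("x", "y", "z"), names(v)),
                          "t1", "r1")]),
    class = "relaxation_map"
  )
}

#' @export
print.relaxation_map <- function(x, ...) {
  n <- sum(x$mask, na.rm = TRUE)
  cat("<relaxation_map> ", n, " accepted voxels; T1 ",
      signif(min(x$t1, na.rm = TRUE), 4), "-",
      signif(max(x$t1, na.rm = TRUE), 4), " s; ",
      x$n_dropped_b_le_a, " voxels dropped (B <= A)\n", sep = "")
  invisible(x)
}

#' Mean R1 within an ROI of a relaxation map
#'
#' @param map A [correct_t1()] relaxation map.
#' @param roi Logical mask matching the map grid.
#' @return Mean R1 (s^-1) over accepted voxels inside the ROI.
#' @export
roi_mean_r1 <- function(map, roi) {
  stopifnot(inherits(map, "relaxation_map"))
  sel <- roi & map$mask
  if (!any(sel)) abort("ROI contains no accepted voxels.")
  mean(map$r1[sel])
}

#' @exportS3Method generics::tidy
tidy.look_locker_fit <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.look_locker_fit <- function(x, ...) {
  v <- as_tibble(x)
  tibble(
    n_voxels = nrow(v),
    n_converged = sum(v$converged),
    n_accepted = sum(v$accepted),
    median_t1_star = stats::median(v$t1_star[v$accepted]),
    median_rel_residual = stats::median(v$rel_residual[v$accepted])
  )
}

#' @exportS3Method generics::tidy
tidy.relaxation_map <- function(x, ...) {
  x$values
}

#' @exportS3Method generics::glance
glance.relaxation_map <- function(x, ...) {
  tibble(
    n_accepted = sum(x$mask, na.rm = TRUE),
    n_dropped_b_le_a = x$n_dropped_b_le_a,
    median_t1 = stats::median(x$t1[x$mask], na.rm = TRUE)
  )
}
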
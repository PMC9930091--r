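# Shared fixtures, all generated in code.

# Noiseless single-voxel Look-Locker magnitude signal for a true T1.
ll_signal_for_t1 <- function(t1, ti, tr_img = 0.025, flip_deg = 5, m0 = 1) {
  t1s <- 1 / (1 / t1 - log(cos(flip_deg * pi / 180)) / tr_img)
  A <- m0 * t1s / t1
  forward_look_locker(A, A + m0, t1s, ti)
}

# Standard in vitro readout: 100 inversion times from 10 ms, spacing 25 ms.
ti_protocol <- function() 0.010 + 0.025 * (0:99)

# Small, fast tube spec used across tests.
small_tube_spec <- function(...) {
  phantom_spec("tube", dim = c(10L, 10L, 24L), voxel_mm = c(0.5, 0.5, 0.5),
               times_h = c(0, 6, 12, 24), ...)
}

# Sphere of `value` in constant background on a cubic grid.
sphere_image <- function(n = 21, radius = 6, value = 2, background = 1) {
  c0 <- (n + 1) / 2
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  r2 <- (g$i - c0)^2 + (g$j - c0)^2 + (g$k - c0)^2
  img <- array(background, dim = c(n, n, n))
  img[r2 <= radius^2] <- value
  list(image = img, truth = array(r2 <= radius^2, dim = c(n, n, n)),
       center = rep(ceiling(c0), 3))
}

# City-block ball mask (what iterated cross erosion/dilation generates).
cityblock_ball <- function(n, radius) {
  c0 <- (n + 1) / 2
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  d <- abs(g$i - c0) + abs(g$j - c0) + abs(g$k - c0)
  array(d <= radius, dim = c(n, n, n))
}

# Release series wrapper for externally computed release fractions.
as_release_series <- function(time_h, fraction) {
  out <- tibble::tibble(time_h = time_h,
                        release_apparent_pct = 100 * fraction,
                        release_corrected_pct = 100 * fraction)
  class(out) <- c("release_series", class(out))
  out
}
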
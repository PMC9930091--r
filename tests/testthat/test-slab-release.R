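test_that("slab release series has the correct limits and monotonicity", {
  expect_equal(simulate_slab_release(1e-11, 5.5e-3, 0), 0)
  expect_equal(simulate_slab_release(1e-11, 5.5e-3, 1e12), 1,
               tolerance = 1e-10)

  t <- seq(0, 5e5, length.out = 40)
  f <- simulate_slab_release(2e-11, 5.5e-3, t)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))

  # monotone in D as well
  f_fast <- simulate_slab_release(4e-11, 5.5e-3, t)
  expect_true(all(f_fast[-1] >= f[-1]))

  expect_error(simulate_slab_release(-1e-11, 5.5e-3, t), "positive")
  expect_error(simulate_slab_release(1e-11, 0, t), "positive")
})

test_that("early-time formula matches the exact series at 30% release", {
  D <- 1e-11; L <- 5.5e-3
  # oracle: invert the 200-term series for the time of 30% release
  t30 <- uniroot(function(t) simulate_slab_release(D, L, t) - 0.30,
                 c(1, 1e9), tol = 1e-6)$root
  approx30 <- early_time_release(D, L, t30)
  expect_equal(approx30, 0.30, tolerance = 0.02)
})

test_that("tube phantom conserves agent mass across refresh events", {
  spec <- small_tube_spec(refresh_h = c(6, 12), D_true = 2e-10)
  ph <- generate_tube_phantom(spec)
  rel <- ph$truth$release
  m0 <- spec$C0_mM * spec$volume_uL[1]

  # mass still in gel at the end
  m_gel_end <- tail(rel$conc_gel_mM * rel$volume_uL, 1)
  # mass sitting in the supernatant at the end
  m_sup_end <- tail(rel$conc_sup_mM, 1) * spec$supernatant_uL
  # mass removed at each refresh (recomputed from the series solution)
  f_at <- function(t) simulate_slab_release(spec$D_true, spec$L_mm * 1e-3,
                                            t * 3600)
  refreshes <- c(0, spec$refresh_h)
  removed <- m0 * sum(diff(f_at(refreshes)))
  expect_equal(m_gel_end + m_sup_end + removed, m0, tolerance = 1e-9)
})

test_that("tube phantom truth matches hand relaxometry arithmetic", {
  # noiseless, no release yet at t = 0: gel R1 exceeds blank R1 by r1 * C0
  spec <- small_tube_spec(sigma = 0, C0_mM = 0.01, r1_true = 95.5)
  ph <- generate_tube_phantom(spec)
  gel <- ph$truth$gel_masks[[1]]
  r1_gel <- 1 / ph$truth$t1_fields[[1]][gel][1]
  expect_equal(r1_gel - 1 / spec$t1_gel_s, 0.955, tolerance = 1e-12)

  # blank phantom: gel voxels carry the blank T1 exactly
  blank <- generate_tube_phantom(small_tube_spec(C0_mM = 0))
  t1g <- blank$truth$t1_fields[[2]][blank$truth$gel_masks[[2]]]
  expect_equal(unique(t1g), blank$spec$t1_gel_s)
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  spec <- small_tube_spec(sigma = 0.02, seed = 7L)
  a <- generate_tube_phantom(spec)
  b <- generate_tube_phantom(spec)
  expect_identical(a$series[[1]]$data, b$series[[1]]$data)
  expect_identical(a$truth$release, b$truth$release)

  other <- generate_tube_phantom(small_tube_spec(sigma = 0.02, seed = 8L))
  expect_false(identical(a$series[[1]]$data, other$series[[1]]$data))
})

test_that("tube volume trajectory is rendered and capacity-checked", {
  spec <- small_tube_spec(volume_uL = c(40, 44, 48, 52))
  ph <- generate_tube_phantom(spec)
  vv <- prod(spec$voxel_mm)
  expect_equal(ph$truth$release$volume_uL,
               round(spec$volume_uL / vv) * vv)
  expect_error(
    generate_tube_phantom(small_tube_spec(volume_uL = c(40, 400, 410, 420))),
    "capacity"
  )
})

test_that("brain phantom renders nested volume trajectories", {
  spec <- phantom_spec("brain", times_h = c(0, 24), volume_uL = c(5, 10))
  ph <- generate_brain_phantom(spec)
  n1 <- sum(ph$truth$gel_masks[[1]])
  n2 <- sum(ph$truth$gel_masks[[2]])
  vv <- prod(spec$voxel_mm)
  # doubling the volume doubles the voxel count within quantisation
  expect_equal(n2 * vv, 2 * n1 * vv, tolerance = vv / (n1 * vv))
  # masks are nested as the gel swells
  expect_true(all(ph$truth$gel_masks[[2]][ph$truth$gel_masks[[1]]]))

  expect_error(
    generate_brain_phantom(
      phantom_spec("brain", times_h = c(0, 24), volume_uL = c(5, 400))),
    "inside the grid"
  )
})

test_that("noisy brain phantom T1 is recovered voxel-wise within 5%", {
  spec <- phantom_spec("brain", dim = c(16L, 16L, 8L),
                       voxel_mm = c(0.3, 0.3, 0.5),
                       times_h = 0, volume_uL = 4,
                       sigma = 0.02, seed = 11L)
  ph <- generate_brain_phantom(spec)
  gel <- ph$truth$gel_masks[[1]]
  s <- ph$series[[1]]
  s$mask <- gel
  map <- correct_t1(fit_look_locker(s))
  truth <- ph$truth$t1_fields[[1]][gel]
  fitted <- map$t1[gel]
  rel_err <- abs(fitted - truth) / truth
  expect_gte(mean(rel_err <= 0.05, na.rm = TRUE), 0.95)
})

test_that("rheology trace follows the saturating exponential", {
  tr <- generate_rheology_trace(3000, tau = 60, times = c(0, 300))
  expect_equal(tr$g_prime_pa[1], 0)
  expect_equal(tr$g_prime_pa[2], 0.9933 * 3000, tolerance = 1e-4)

  # plateau estimator recovers G_inf from a noisy tail within the noise SD
  times <- seq(0, 5 * 3600, by = 60)
  noisy <- generate_rheology_trace(3000, tau = 1800, times = times,
                                   noise_sd = 50, seed = 3L)
  pl <- estimate_plateau(noisy, tail_fraction = 0.2)
  expect_lt(abs(pl$g_plateau_pa - 3000), 50)
  expect_error(generate_rheology_trace(-1, 60, 0), "positive")
})
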
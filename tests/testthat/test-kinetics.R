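test_that("cumulative release reproduces hand arithmetic", {
  d <- tibble::tibble(time_h = c(0, 24), conc_mM = c(1.0, 0.5),
                      volume_uL = c(40, 50))
  rel <- cumulative_release(d)
  expect_equal(rel$release_corrected_pct, c(0, 37.5))
  expect_equal(rel$release_apparent_pct, c(0, 50))

  # concentration halves at constant volume: 50% release either way
  d2 <- tibble::tibble(time_h = c(0, 10), conc_mM = c(2, 1),
                       volume_uL = c(40, 40))
  rel2 <- cumulative_release(d2)
  expect_equal(rel2$release_corrected_pct[2], 50)

  expect_error(
    cumulative_release(tibble::tibble(time_h = c(0, 1), conc_mM = c(0, 1),
                                      volume_uL = c(1, 1))),
    "positive"
  )
  expect_error(
    cumulative_release(tibble::tibble(time_h = c(1, 1), conc_mM = c(1, 1),
                                      volume_uL = c(1, 1))),
    "increasing"
  )
})

test_that("release is invariant to joint rescaling of units", {
  d <- tibble::tibble(time_h = c(0, 6, 24),
                      conc_mM = c(1.0, 0.7, 0.4),
                      volume_uL = c(40, 45, 55))
  base <- cumulative_release(d)
  scaled <- cumulative_release(
    dplyr::mutate(d, conc_mM = conc_mM * 74, volume_uL = volume_uL / 1000))
  expect_equal(scaled$release_corrected_pct, base$release_corrected_pct)
})

test_that("sqrt-time regression recovers exact linear kinetics", {
  t <- c(1, 4, 9, 16)
  rel <- as_release_series(t, 0.1 * sqrt(t))   # release% = 10 sqrt(t)
  fit <- sqrt_time_fit(rel, window = c(0, 24))
  expect_equal(fit$k, 10, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  shuffled <- rel[c(2, 1, 3, 4), ]
  expect_error(sqrt_time_fit(shuffled), "increasing")
  expect_error(sqrt_time_fit(rel, window = c(0, 1)), "three time points")
})

test_that("sqrt-time fit matches the analytic early-time Fickian slope", {
  D <- 7e-11; L <- 5.5e-3
  th <- seq(0.25, 24, by = 0.25)
  f <- simulate_slab_release(D, L, th * 3600)
  fit <- sqrt_time_fit(as_release_series(th, f), window = c(0, 24))
  k_analytic <- 100 * 4 * sqrt(D / (pi * (2 * L)^2)) * sqrt(3600)
  expect_equal(fit$k, k_analytic, tolerance = 0.05)
  expect_gte(fit$r_squared, 0.99)
})

test_that("diffusion inversion reproduces hand arithmetic and scaling", {
  res <- diffusion_from_rate(10.3, 5.5e-3)
  expect_equal(res$D_m2_s, 7.0e-11, tolerance = 0.01)

  # doubling k quadruples D
  expect_equal(diffusion_from_rate(20.6, 5.5e-3)$D_m2_s / res$D_m2_s, 4,
               tolerance = 1e-12)

  # two-sided geometry halves the diffusional thickness: D is 4x smaller
  expect_equal(diffusion_from_rate(10.3, 5.5e-3, "two_sided")$D_m2_s,
               res$D_m2_s / 4, tolerance = 1e-12)

  # hindrance factor against water
  expect_equal(
    diffusion_from_rate(10.3, 5.5e-3, D_water = 7e-10)$factor_vs_water,
    7e-10 / res$D_m2_s, tolerance = 1e-12)

  expect_error(diffusion_from_rate(-1, 5.5e-3), "positive")
})

test_that("D -> simulate -> fit -> D round trip closes within 10%", {
  L <- 5.5e-3
  for (D in c(2e-11, 7e-11)) {
    th <- seq(0.5, 24, by = 0.5)
    f <- simulate_slab_release(D, L, th * 3600)
    keep <- f <= 0.4
    fit <- sqrt_time_fit(as_release_series(th[keep], f[keep]),
                         window = c(0, 24))
    D_rec <- diffusion_from_rate(fit, L)$D_m2_s
    expect_equal(D_rec, D, tolerance = 0.1)
  }
})

test_that("mesh size matches the rubber-elasticity closed form", {
  res <- mesh_size(c(3000, 6300), T = 310)
  expect_equal(round(res$mesh_nm, 1), c(11.3, 8.8))
  expect_equal(res$verdict, c("diffusive", "diffusive"))

  # direct arithmetic cross-check
  expect_equal(res$mesh_nm[1],
               (8.314 * 310 / (3000 * 6.022e23))^(1 / 3) * 1e9,
               tolerance = 1e-12)

  # eightfold modulus halves the mesh; decreasing in G', increasing in T
  expect_equal(mesh_size(8 * 3000, T = 310)$mesh_nm, res$mesh_nm[1] / 2,
               tolerance = 1e-12)
  g <- mesh_size(c(1000, 2000, 4000, 8000))$mesh_nm
  expect_true(all(diff(g) < 0))
  tt <- vapply(c(290, 300, 310, 320),
               function(T) mesh_size(3000, T = T)$mesh_nm, numeric(1))
  expect_true(all(diff(tt) > 0))

  # a large protein in a tight mesh is hindered
  expect_equal(mesh_size(3000, T = 310, diameter_nm = 12)$verdict, "hindered")
  expect_error(mesh_size(-1), "positive")
})

test_that("plateau estimation averages the trace tail", {
  const <- tibble::tibble(time_s = 1:10, g_prime_pa = rep(1234, 10))
  expect_equal(estimate_plateau(const)$g_plateau_pa, 1234)

  times <- seq(0, 5 * 3600, by = 60)
  tr <- generate_rheology_trace(3000, tau = 1800, times = times)
  pl <- estimate_plateau(tr, tail_fraction = 0.2)
  expect_equal(pl$g_plateau_pa, 3000, tolerance = 1e-3)
  expect_error(estimate_plateau(const, tail_fraction = 0), "tail_fraction")
})

test_that("IVIVR comparison interpolates and guards its span", {
  vitro <- as_release_series(c(0, 24, 144), c(0, 0.38, 0.64))
  vivo <- as_release_series(c(0, 48, 144), c(0, 0.69, 0.83))

  # identical series give zero differences
  same <- ivivr_table(vitro, vitro, c(24, 144))
  expect_equal(same$difference_pp, c(0, 0))

  tab <- ivivr_table(vitro, vivo, 144)
  expect_equal(tab$in_vitro_pct, 64)
  expect_equal(tab$in_vivo_pct, 83)
  expect_equal(tab$difference_pp, 19)

  expect_error(ivivr_table(vitro, vivo, 200), "shared span")
  late <- as_release_series(c(200, 300), c(0.1, 0.2))
  expect_error(ivivr_table(vitro, late, 100), "overlap")
})

test_that("rate-constant comparison flags genuinely different slopes", {
  t <- seq(1, 24, by = 1)
  fast <- as_release_series(t, pmin(0.103 * sqrt(t), 1))
  slow <- as_release_series(t, pmin(0.075 * sqrt(t), 1))
  cmp <- compare_release_rates(fast, slow, labels = c("LC", "HC"))
  expect_equal(cmp$k_a, 10.3, tolerance = 1e-6)
  expect_equal(cmp$k_b, 7.5, tolerance = 1e-6)
  expect_equal(cmp$k_diff, 2.8, tolerance = 1e-6)
  expect_lt(cmp$p_value, 1e-6)
})
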
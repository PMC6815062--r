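default_inputs <- function(ka) {
  scattering_inputs_from_model(default_bone_model(), ka = ka)
}

dj <- function(x, m) if (m == 0) -besselJ(x, 1) else (besselJ(x, m - 1) - besselJ(x, m + 1)) / 2
dy <- function(x, m) if (m == 0) -besselY(x, 1) else (besselY(x, m - 1) - besselY(x, m + 1)) / 2

test_that("a vanishing scatterer produces no phase shift", {
  si <- default_inputs(1e-6)
  expect_lt(abs(phase_shift(0, si)), 1e-6)
})

test_that("the immovable-rigid limit recovers the classical phase shifts", {
  # density_ratio -> 0 decouples the interior: eta_m -> arctan(-J'_m/N'_m)
  x <- 0.5
  si <- scattering_inputs(x, 5, 9, density_ratio = 1e-12, poisson_ratio = 0.24)
  for (m in 0:3) {
    expect_equal(phase_shift(m, si), atan(-dj(x, m) / dy(x, m)),
                 tolerance = 1e-8)
  }
})

test_that("phase shifts match the high-precision oracle at ka = 0.5", {
  si <- default_inputs(0.5)
  expect_equal(tan(phase_shift(0:3, si)), oracle_tan_eta_ka05,
               tolerance = 1e-10)
})

test_that("the cross-section matches the oracle on 20 seeded parameter draws", {
  draws <- oracle_draws()
  for (i in seq_len(nrow(draws))) {
    si <- draw_inputs(draws$ka[i], draws$nu[i], draws$density_ratio[i])
    gam <- scattering_cross_section(si, radius = 1)
    expect_equal(gam, draws$gamma_ref[i], tolerance = 1e-8,
                 label = sprintf("gamma at draw %d (ka=%.3f)", i, draws$ka[i]))
  }
})

test_that("the cross-section matches the oracle across ka at default materials", {
  for (i in seq_len(nrow(oracle_gamma_default))) {
    si <- default_inputs(oracle_gamma_default$ka[i])
    expect_equal(scattering_cross_section(si, radius = 1),
                 oracle_gamma_default$gamma_ref[i], tolerance = 1e-10)
  }
})

test_that("the rigid long-wavelength limit approaches 3 pi^2 / 4", {
  ka <- 1e-3
  si <- scattering_inputs(ka, 5, 9, density_ratio = 1e-12,
                          poisson_ratio = 0.24)
  coef <- scattering_cross_section(si, radius = 1) / ka^3
  expect_equal(coef, 3 * pi^2 / 4, tolerance = 1e-3)
  # rayleigh_limit() is exactly that coefficient
  expect_equal(rayleigh_limit(ka, 1) / ka^3, 3 * pi^2 / 4, tolerance = 1e-12)
})

test_that("rayleigh_limit scales cubically and handles ka = 0", {
  expect_equal(rayleigh_limit(0, 1e-4), 0)
  expect_equal(rayleigh_limit(2e-3, 1e-4) / rayleigh_limit(1e-3, 1e-4), 8)
  expect_equal(rayleigh_limit(1e-3, 1e-4), 0.75 * pi^2 * 1e-9 * 1e-4)
})

test_that("the elastic long-wavelength coefficient matches the closed form", {
  m <- default_bone_model()
  coef_cf <- elastic_rayleigh_coefficient(m)
  kas <- c(1e-1, 1e-2, 1e-3)
  coefs <- vapply(kas, function(ka) {
    scattering_cross_section(default_inputs(ka), radius = 1) / ka^3
  }, numeric(1))
  # monotone convergence from below toward the closed form
  expect_true(all(diff(abs(coefs - coef_cf)) < 0))
  expect_equal(coefs[3], coef_cf, tolerance = 1e-4)
  # the elastic coefficient is smaller than the rigid-limit coefficient
  expect_lt(coef_cf, 3 * pi^2 / 4)
})

test_that("the angular pattern is symmetric and integrates to the cross-section", {
  for (ka in c(0.25, 0.5)) {
    si <- default_inputs(ka)
    th <- seq(-pi, pi, length.out = 721)
    pat <- angular_intensity(th, si)
    expect_equal(pat$intensity, rev(pat$intensity), tolerance = 1e-12)

    # quadrature of the raw pattern times the far-field prefactor
    a <- 1
    th2 <- seq(0, 2 * pi, length.out = 2001)
    raw <- angular_intensity(th2, si, normalize = FALSE)$intensity
    h <- th2[2] - th2[1]
    integral <- h * (sum(raw) - (raw[1] + raw[length(raw)]) / 2)
    gamma_quad <- 2 * a / (pi * ka) * integral
    expect_equal(gamma_quad, scattering_cross_section(si, radius = a),
                 tolerance = 1e-6)
  }
})

test_that("backscattering dominates forward scattering at long wavelengths", {
  # lambda = 8 pi a (ka = 0.25) and lambda = 4 pi a (ka = 0.5)
  for (ka in c(0.25, 0.5)) {
    si <- default_inputs(ka)
    pat <- angular_intensity(c(0, pi), si)
    expect_gt(pat$intensity[2], pat$intensity[1])
  }
})

test_that("series truncation is stable to 1e-10", {
  for (ka in c(0.5, 2, 5)) {
    si <- default_inputs(ka)
    gam <- scattering_cross_section(si, radius = 1)
    ser <- boneatten:::faran_series(si)
    m_ext <- ser$m_max + 15L
    sin2 <- vapply(0:m_ext, function(m) {
      boneatten:::eta_terms(m, si)$sin2
    }, numeric(1))
    eps <- c(1, rep(2, m_ext))
    gam_ext <- (4 / ka) * sum(eps * sin2)
    expect_equal(gam, gam_ext, tolerance = 1e-10)
  }
})

test_that("the cross-section is continuous in ka (no arctan branch spikes)", {
  ka <- seq(0.8, 0.9, by = 1e-3)
  gam <- vapply(ka, function(k) {
    scattering_cross_section(default_inputs(k), radius = 1)
  }, numeric(1))
  rel_jump <- abs(diff(gam)) / gam[-length(gam)]
  expect_lt(max(rel_jump), 0.01)
})

test_that("gamma_vs_ka returns the grid, normalization and nonlinearity", {
  m <- default_bone_model()
  one <- gamma_vs_ka(0.5, m)
  expect_equal(nrow(one), 1L)
  expect_equal(one$gamma_sca, oracle_gamma_default$gamma_ref[3] * m$radius,
               tolerance = 1e-10)

  grid <- seq(0.1, 1, length.out = 19)
  tab <- gamma_vs_ka(grid, m)
  expect_equal(max(tab$gamma_normalized), 1)
  # nonlinear in ka: second differences on the uniform grid are non-zero
  second <- diff(tab$gamma_sca, differences = 2)
  expect_gt(max(abs(second)) / max(tab$gamma_sca), 1e-4)
  expect_error(gamma_vs_ka(c(0.5, 0.4), m), "increasing")
})

test_that("the published transcription of the boundary angle is not the classical one", {
  # the 'printed' variant carries typographical errors; it disagrees with
  # the oracle-validated corrected form everywhere except trivially
  si <- default_inputs(0.5)
  g_corr <- scattering_cross_section(si, radius = 1)
  g_prt <- scattering_cross_section(si, radius = 1, xi_form = "printed")
  expect_gt(abs(g_prt - g_corr) / g_corr, 0.1)
  expect_equal(g_corr, oracle_gamma_default$gamma_ref[3], tolerance = 1e-10)
})

test_that("scattering input validation rejects impossible configurations", {
  expect_error(scattering_inputs(-1, 1, 2, 0.5, 0.2), "ka")
  expect_error(scattering_inputs(0.5, 2, 1, 0.5, 0.2), "x1 must be smaller")
  expect_error(scattering_inputs(0.5, 1, 2, -1, 0.2), "density_ratio")
  expect_error(angular_intensity(numeric(0), default_inputs(0.5)),
               "non-empty")
  expect_error(scattering_inputs_from_model(default_bone_model()),
               "exactly one")
})
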
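synthetic_spectrum <- function(f, alpha) {
  tibble::tibble(f_mhz = f, alpha_total = alpha)
}

test_that("bua recovers exact lines", {
  f <- seq(0.3, 0.65, length.out = 20)
  fit <- bua(synthetic_spectrum(f, 10 * f))
  expect_equal(fit$slope, 10, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  fit2 <- bua(synthetic_spectrum(f, 3 + 2 * f))
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$intercept, 3, tolerance = 1e-12)
})

test_that("bua slope is invariant to adding a constant", {
  f <- seq(0.3, 0.65, length.out = 50)
  spec <- total_attenuation(f, default_bone_model())
  f1 <- bua(spec)
  shifted <- synthetic_spectrum(spec$f_mhz, spec$alpha_total + 5)
  f2 <- bua(shifted)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
})

test_that("bua validates band coverage", {
  f <- seq(0.3, 0.65, length.out = 20)
  expect_error(bua(synthetic_spectrum(f, 10 * f), f_band = c(0.8, 1)),
               "at least 5 points")
})

test_that("bua on the default model matches the oracle", {
  spec <- total_attenuation(seq(0.3, 0.65, length.out = 50),
                            default_bone_model())
  fit <- bua(spec)
  expect_equal(fit$slope, oracle_defaults$bua_slope, tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle_defaults$bua_r2, tolerance = 1e-10)
  # quasi-linear over the clinical band at the honestly computed level
  expect_gt(fit$r_squared, 0.98)
})

test_that("powerlaw_exponent recovers planted power laws exactly", {
  f <- seq(0.3, 0.65, length.out = 50)
  for (p in seq(0.5, 3.5, by = 0.5)) {
    fit <- powerlaw_exponent(f, 2.7 * f^p)
    expect_equal(fit$exponent, p, tolerance = 1e-10)
    expect_equal(fit$prefactor, 2.7, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
  expect_error(powerlaw_exponent(f, -f), "positive")
  expect_error(powerlaw_exponent(c(1, 2, 3), c(1, 2, 3)), "at least 5")
})

test_that("the scattering component's exponent matches the oracle", {
  spec <- total_attenuation(seq(0.3, 0.65, length.out = 50),
                            default_bone_model())
  fit <- powerlaw_exponent(spec$f_mhz, spec$alpha_scattering)
  expect_equal(fit$exponent, oracle_defaults$exponent, tolerance = 1e-8)
  # insensitive to grid density
  for (n in c(25, 200)) {
    s <- total_attenuation(seq(0.3, 0.65, length.out = n),
                           default_bone_model())
    e <- powerlaw_exponent(s$f_mhz, s$alpha_scattering)$exponent
    expect_equal(e, fit$exponent, tolerance = 5e-3)
  }
})

test_that("the absorption/scattering crossover sits where the oracle says", {
  res <- crossover_frequency(default_bone_model())
  expect_equal(res$status, "ok")
  expect_equal(res$crossover_mhz, oracle_defaults$crossover_mhz,
               tolerance = 2e-4)
  expect_true(res$crossover_mhz > 0.5 && res$crossover_mhz < 0.7)

  # scattering dominates everywhere above the crossover within the range
  m <- default_bone_model()
  f_above <- seq(res$crossover_mhz + 0.01, 1.5, length.out = 15)
  spec <- total_attenuation(f_above, m)
  expect_true(all(spec$alpha_scattering > spec$alpha_absorption))
  # and absorption below it
  f_below <- seq(0.1, res$crossover_mhz - 0.01, length.out = 15)
  spec_b <- total_attenuation(f_below, m)
  expect_true(all(spec_b$alpha_scattering < spec_b$alpha_absorption))
})

test_that("no crossover is reported when scattering is absent", {
  res <- crossover_frequency(set_porosity(default_bone_model(), 1))
  expect_equal(res$status, "no_crossover")
  expect_true(is.na(res$crossover_mhz))
})

test_that("porosity sweeps are affine in attenuation and decreasing in BUA", {
  m <- default_bone_model()
  poro <- seq(0.7, 0.95, by = 0.05)
  at <- porosity_sweep(m, poro, f = 0.5)
  expect_equal(nrow(at), length(poro))
  second <- diff(at$alpha_total, differences = 2)
  expect_lt(max(abs(second)), 1e-12 * max(at$alpha_total))
  expect_true(all(diff(at$alpha_total) < 0))
  expect_true(all(at$radius_m == m$radius))

  single <- porosity_sweep(m, 0.8, f = 0.5)
  expect_equal(single$alpha_total, total_attenuation(0.5, m)$alpha_total)

  slopes <- porosity_sweep(m, poro, f_band = c(0.3, 0.65), n_points = 12L)
  expect_true(all(diff(slopes$bua_db_cm_mhz) < 0))
})

test_that("size sweep stacks spectra and keeps the component identity", {
  m <- default_bone_model()
  f <- seq(0.3, 0.65, length.out = 6)
  one <- size_sweep(m, m$radius, f)
  ref <- total_attenuation(f, m)
  expect_equal(one$alpha_total, ref$alpha_total)

  sw <- size_sweep(m, c(70, 100, 150) * 1e-6, 0.5)
  expect_true(all(diff(sw$alpha_total) > 0))
  expect_equal(sw$alpha_total, sw$alpha_absorption + sw$alpha_scattering)
})

test_that("fits expose broom-style tidiers", {
  spec <- total_attenuation(seq(0.3, 0.65, length.out = 50),
                            default_bone_model())
  fit <- bua(spec)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- glance(fit)
  expect_equal(gl$r_squared, fit$r_squared)

  pf <- powerlaw_exponent(spec$f_mhz, spec$alpha_scattering)
  expect_equal(tidy(pf)$estimate[2], pf$exponent)
  expect_equal(glance(pf)$r_squared, pf$r_squared)
})
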
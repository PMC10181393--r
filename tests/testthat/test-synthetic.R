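zero_noise_cfg <- function(arch, replicates = 2, seed = 1) {
  synthetic_config(arch, replicates = replicates, seed = seed,
                   noise_sd_dim = 0, noise_sd_length = 0,
                   noise_sd_mass = 0, noise_sd_density = 0)
}

test_that("zero-noise records close the loop with the analytical model", {
  for (arch in arch_codes) {
    cfg <- zero_noise_cfg(arch)
    rec <- generate_measurements(cfg)
    red <- reduce_measurements(rec, rho_f = cfg$rho_f)
    fr <- analytical_fractions(arch, cfg$params)
    expect_equal(red$C_w, rec$true_C_w)
    expect_equal(red$C_f, rec$true_C_f)
    expect_equal(red$C_z, rec$true_C_z)
    expect_equal(red$V_fw, rep(fr$V_fw, 2))
    expect_equal(red$V_ff, rep(fr$V_ff, 2))
    expect_equal(red$V_fz, rep(fr$V_fz, 2))
    expect_equal(red$V_fp, rep(fr$V_fp, 2))
    # and micromechanics downstream agrees between the two routes
    m_red <- scaffold_mechanics(fraction_set(red$V_fw[1], red$V_ff[1],
                                             red$V_fz[1]))
    m_an <- scaffold_mechanics(fraction_set(fr$V_fw, fr$V_ff, fr$V_fz))
    expect_equal(m_red$E_p, m_an$E_p)
    expect_equal(m_red$sigma_33, m_an$sigma_33)
  }
})

test_that("reference crimps regenerate from a matching configuration", {
  p <- default_cell_params("3DW-P-ZP")
  cfg <- zero_noise_cfg("3DW-P-ZP")
  red <- reduce_measurements(generate_measurements(cfg))
  expect_equal(red$C_w[1], 5.55, tolerance = 1e-6)
  expect_equal(red$C_f[1], 14.28, tolerance = 1e-6)
  expect_equal(red$C_z[1], 50.00, tolerance = 1e-6)
})

test_that("generation is reproducible from its seed", {
  cfg <- synthetic_config("3DW-P-ZO", replicates = 5, seed = 99)
  a <- generate_measurements(cfg)
  b <- generate_measurements(cfg)
  expect_identical(a, b)
  # byte-identical CSV output
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(a, f1)
  write_measurements(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed moves the noise
  c2 <- generate_measurements(synthetic_config("3DW-P-ZO", replicates = 5,
                                               seed = 100))
  expect_false(identical(a$rho_p, c2$rho_p))
})

test_that("impossible noise levels fail loudly after bounded redraws", {
  cfg <- synthetic_config("3DW-O-ZO", replicates = 1, seed = 3,
                          noise_sd_density = 1e6)
  expect_error(suppressWarnings(generate_measurements(cfg)), "100 attempts")
})

test_that("recovery is exact at zero noise", {
  out <- recovery_experiment(zero_noise_cfg("3DW-P-ZP", replicates = 5))
  expect_equal(out$bias, rep(0, nrow(out)), tolerance = 1e-10)
  expect_equal(out$rmse, rep(0, nrow(out)), tolerance = 1e-10)
})

test_that("crimp recovery error scales linearly with length noise", {
  rmse_at <- function(sd, seed) {
    cfg <- synthetic_config("3DW-O-ZO", replicates = 400, seed = seed,
                            noise_sd_dim = 0, noise_sd_length = sd,
                            noise_sd_mass = 0, noise_sd_density = 0)
    out <- recovery_experiment(cfg)
    out$rmse[out$quantity == "C_w"]
  }
  r1 <- rmse_at(0.1, 21)
  r2 <- rmse_at(0.2, 22)
  # doubling the SD should double the RMSE (delta method); simulation slack
  expect_equal(r2 / r1, 2, tolerance = 0.25)
})

test_that("total-fraction recovery is unbiased under additive density noise", {
  cfg <- synthetic_config("3DW-P-ZO", replicates = 600, seed = 5,
                          noise_sd_dim = 0, noise_sd_length = 0,
                          noise_sd_mass = 0, noise_sd_density = 0.02)
  out <- recovery_experiment(cfg)
  bias <- out$bias[out$quantity == "V_fp"]
  # bias of 100/rho_f * mean(noise): SE = 100/1.5 * 0.02/sqrt(600) ~ 0.054
  expect_lt(abs(bias), 3 * 100 / 1.5 * 0.02 / sqrt(600))
})
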
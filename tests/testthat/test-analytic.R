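test_that("unit-cell volume matches hand-evaluated products", {
  expect_equal(unit_cell_volume("3DW-P-ZP", unit_params()), 18)
  expect_equal(unit_cell_volume("3DW-P-ZO", unit_params()), 18)
  expect_equal(unit_cell_volume("3DW-O-ZO", unit_params()), 27)
  # (2*0.5 + 3*0.5)(2*0.5 + 2*0.5)(1*0.5 + 2*0.5) = 2.5 * 2 * 1.5 = 7.5
  expect_equal(
    unit_cell_volume("3DW-P-ZP",
                     unit_params(N = 2, M = 2, T = 1,
                                 d_w = 0.5, d_f = 0.5, d_z = 0.5)),
    7.5
  )
})

test_that("plain warp fraction reproduces the symbolic unit-cell value", {
  # N=M=T=1, unit diameters: V_w = 1*1*(1+2)*(pi/4) = 3 pi/4; V_p = 18
  fr <- analytical_fractions("3DW-P-ZP", unit_params())
  expect_equal(fr$V_fw, 100 * (3 * pi / 4) / 18, tolerance = 1e-12)
})

test_that("crimp enters only its own numerator", {
  for (arch in c("3DW-P-ZP", "3DW-P-ZO")) {
    base <- analytical_fractions(arch, unit_params(d_w = 0.5, d_f = 0.5,
                                                   d_z = 0.5))
    crimped <- analytical_fractions(arch, unit_params(d_w = 0.5, d_f = 0.5,
                                                      d_z = 0.5, C_w = 0.10))
    expect_equal(crimped$V_fw, 1.10 * base$V_fw)
    expect_equal(crimped$V_ff, base$V_ff)
    expect_equal(crimped$V_fz, base$V_fz)
  }
  # orthogonal carries no crimp factors at all
  o0 <- analytical_fractions("3DW-O-ZO", unit_params())
  o1 <- analytical_fractions("3DW-O-ZO", unit_params(C_w = 0.3, C_f = 0.3,
                                                     C_z = 0.3))
  expect_equal(unclass(o1), unclass(o0))
})

test_that("semi-interlaced z-yarn crimp is off verbatim, on by request", {
  p <- unit_params(C_z = 0.3333)
  verbatim <- analytical_fractions("3DW-P-ZO", p)
  applied <- analytical_fractions("3DW-P-ZO", p, semi_z_crimp = "apply")
  expect_equal(applied$V_fz, 1.3333 * verbatim$V_fz)
  expect_equal(applied$V_fw, verbatim$V_fw)
  # with the switch on, semi matches plain at zero z-interlacement crimp diff
  plain <- analytical_fractions("3DW-P-ZP", p)
  expect_equal(applied$V_fz, plain$V_fz)
})

test_that("fraction-sum and porosity-complement identities hold at machine precision", {
  for (arch in arch_codes) {
    for (p in param_grid()) {
      fr <- analytical_fractions(arch, p)
      expect_equal(fr$V_fw + fr$V_ff + fr$V_fz, fr$V_fp, tolerance = 1e-12)
      expect_equal(fr$V_fp + fr$V_tpr, 100, tolerance = 1e-12)
      expect_equal(fr$V_wpr, fr$V_tpr / 3, tolerance = 1e-12)
      expect_equal(fr$V_wpr, fr$V_fpr)
      expect_equal(fr$V_fpr, fr$V_zpr)
    }
  }
})

test_that("fractions are invariant under uniform diameter rescaling", {
  for (arch in arch_codes) {
    p <- unit_params(N = 2, M = 3, T = 2, d_w = 0.4, d_f = 0.5, d_z = 0.3,
                     C_w = 0.05, C_f = 0.14, C_z = 0.5)
    fr1 <- analytical_fractions(arch, p)
    for (k in c(0.1, 3)) {
      pk <- unit_params(N = 2, M = 3, T = 2, d_w = 0.4 * k, d_f = 0.5 * k,
                        d_z = 0.3 * k, C_w = 0.05, C_f = 0.14, C_z = 0.5)
      frk <- analytical_fractions(arch, pk)
      expect_equal(frk$V_fw, fr1$V_fw, tolerance = 1e-12)
      expect_equal(frk$V_fp, fr1$V_fp, tolerance = 1e-12)
    }
  }
})

test_that("directional fractions grow with their own crimp and diameter", {
  crimps <- seq(0, 0.5, by = 0.1)
  vals <- vapply(crimps, function(cw) {
    analytical_fractions("3DW-P-ZP", unit_params(C_w = cw))$V_fw
  }, 0)
  expect_true(all(diff(vals) > 0))
  # z fraction vs its own diameter, other diameters fixed
  dzs <- seq(0.2, 1, by = 0.2)
  vz <- vapply(dzs, function(dz) {
    analytic <- analytical_fractions("3DW-O-ZO", unit_params(d_z = dz))
    analytic$V_fz * unit_cell_volume("3DW-O-ZO", unit_params(d_z = dz))
  }, 0)
  # numerator (volume) must grow faster than d^2 would alone
  expect_true(all(diff(vz) > 0))
})

test_that("non-physical geometries are flagged, not clamped", {
  p <- unit_params(N = 1, M = 1, T = 1, d_w = 1, d_f = 1, d_z = 1,
                   C_w = 3, C_f = 3, C_z = 3)
  expect_warning(fr <- analytical_fractions("3DW-P-ZP", p), "non-physical")
  expect_true(attr(fr, "non_physical"))
  expect_gt(fr$V_fp, 100)
  expect_lt(fr$V_tpr, 0)
})

test_that("porosity complement is exact and validates its domain", {
  expect_equal(porosity_complement(53.52), 46.48)
  expect_equal(porosity_complement(37.08), 62.92)
  expect_equal(porosity_complement(0), 100)
  expect_error(porosity_complement(120), "0, 100")
  expect_error(porosity_complement(-1), "0, 100")
})

test_that("fraction sets accept an independently measured total", {
  fs <- fraction_set(20.06, 7.03, 9.55, V_fp = 36.66)
  expect_equal(fs$V_fp, 36.66)
  expect_equal(fs$V_tpr, 63.34)
  expect_false(attr(fs, "additive"))
  fs2 <- fraction_set(10, 10, 10)
  expect_true(attr(fs2, "additive"))
  expect_equal(fs2$V_fp, 30)
})
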
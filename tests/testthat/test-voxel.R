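test_that("voxel fractions partition the grid exactly", {
  p <- unit_params(N = 2, M = 2, T = 2, d_w = 0.5, d_f = 0.5, d_z = 0.5)
  for (arch in arch_codes) {
    cell <- build_unit_cell(arch, p, resolution = 48)
    fr <- voxel_fractions(cell)
    void <- 100 * mean(cell$labels == 0L)
    expect_identical(fr$V_fw + fr$V_ff + fr$V_fz + void, 100)
    expect_equal(fr$V_tpr, void, tolerance = 1e-12)
    expect_true(attr(fr, "additive"))
  }
})

test_that("straight-yarn occupancy converges to the continuum cylinder volume", {
  # orthogonal cell: every yarn is a straight cylinder, so the voxel count
  # must approach (sum of count x span x pi d^2/4) / V_p as the grid refines
  p <- unit_params(N = 1, M = 1, T = 1)
  target <- 100 * sum(build_unit_cell("3DW-O-ZO", p,
                                      resolution = 20)$ideal_volumes) /
    unit_cell_volume("3DW-O-ZO", p)
  err <- vapply(c(20, 40, 80), function(res) {
    fr <- voxel_fractions(build_unit_cell("3DW-O-ZO", p, resolution = res))
    abs(fr$V_fp - target)
  }, 0)
  expect_lt(err[3], 1)            # close at the finest grid
  expect_lt(err[3], err[1])       # and closer than at the coarsest
})

test_that("voxel estimate is Cauchy in resolution for fixed geometry", {
  p <- default_cell_params("3DW-O-ZO")
  v <- vapply(c(10, 20, 40, 80), function(res) {
    suppressWarnings(
      voxel_fractions(build_unit_cell("3DW-O-ZO", p, resolution = res))$V_fp
    )
  }, 0)
  deltas <- abs(diff(v))
  expect_lt(deltas[3], deltas[1])
})

test_that("orthogonal voxel cell agrees with the analytical oracle", {
  p <- default_cell_params("3DW-O-ZO")
  an <- analytical_fractions("3DW-O-ZO", p)
  vx <- voxel_fractions(build_unit_cell("3DW-O-ZO", p, resolution = 48))
  expect_lt(abs(an$V_fp - vx$V_fp), 3)
})

test_that("plain voxel cell stays within the analytic band at stated params", {
  p <- default_cell_params("3DW-P-ZP")
  an <- analytical_fractions("3DW-P-ZP", p)
  cell <- build_unit_cell("3DW-P-ZP", p, resolution = 48)
  vx <- voxel_fractions(cell)
  expect_lt(abs(an$V_fp - vx$V_fp), 5)
  expect_true(all(c(vx$V_fw, vx$V_ff, vx$V_fz) >= 0))
  expect_true(vx$V_fp <= 100)
  # interlaced paths really are crimped, and the builder reports it
  expect_gt(cell$achieved_crimps[["warp"]], 0)
  expect_gt(cell$achieved_crimps[["z"]], 0)
})

test_that("priority claiming never creates fiber volume", {
  for (arch in arch_codes) {
    p <- default_cell_params(arch)
    cell <- build_unit_cell(arch, p, resolution = 40)
    fiber_vol <- sum(cell$labels > 0L) * prod(cell$voxel_size)
    # bound: continuum volume of all yarns, plus a small discretization
    # margin for boundary voxels
    expect_lt(fiber_vol, 1.02 * sum(cell$ideal_volumes))
  }
})

test_that("the builder is deterministic and warns at coarse resolution", {
  p <- default_cell_params("3DW-P-ZO")
  a <- build_unit_cell("3DW-P-ZO", p, resolution = 40)
  b <- build_unit_cell("3DW-P-ZO", p, resolution = 40)
  expect_identical(a$labels, b$labels)
  expect_warning(build_unit_cell("3DW-P-ZO", p, resolution = 10),
                 "resolution")
})

test_that("alternative cross-sections rasterize and keep the partition", {
  p <- unit_params(N = 1, M = 1, T = 1)
  for (cs in c("ellipse", "lenticular")) {
    fr <- voxel_fractions(build_unit_cell("3DW-O-ZO", p, resolution = 24,
                                          cross_section = cs))
    expect_true(fr$V_fp > 0 && fr$V_fp < 100)
    expect_equal(fr$V_fp + fr$V_tpr, 100, tolerance = 1e-12)
  }
  # lenticular section is thinner than the circle, so it packs less fiber
  circ <- voxel_fractions(build_unit_cell("3DW-O-ZO", p, resolution = 32))
  lent <- voxel_fractions(build_unit_cell("3DW-O-ZO", p, resolution = 32,
                                          cross_section = "lenticular"))
  expect_lt(lent$V_fp, circ$V_fp)
})

test_that("voxel export writes a readable raw grid, header and VTK file", {
  p <- unit_params(N = 1, M = 1, T = 1)
  cell <- build_unit_cell("3DW-O-ZO", p, resolution = 20)
  prefix <- withr::local_tempfile()
  paths <- write_voxel_cell(cell, prefix)
  hdr <- jsonlite::read_json(paths[["json"]])
  expect_equal(unlist(hdr$shape), dim(cell$labels))
  bytes <- readBin(paths[["raw"]], "raw", n = length(cell$labels) + 10)
  expect_equal(length(bytes), length(cell$labels))
  expect_equal(as.integer(bytes), as.integer(cell$labels))
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_voxel_vtk(cell, vtk)
  head_lines <- readLines(vtk, n = 5)
  expect_match(head_lines[4], "STRUCTURED_POINTS")
})
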
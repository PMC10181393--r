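#' Unit-cell volume of a 3D woven preform
#'
#' The repeat box is the product of three yarn-packing spans:
#' thickness `M d_w + (M+1) d_z`, width `N d_w + N d_f` (plain and
#' semi-interlaced) or `N d_w + (N+1) d_f` (orthogonal), and length
#' `T d_f + (T+1) d_z`.
#'
#' @param arch Architecture code or [preform_architecture()].
#' @param p A [unit_cell_params()] object.
#' @return Unit-cell volume in mm^3.
#' @examples
#' p <- unit_cell_params(1, 1, 1, 1, 1, 1)
#' unit_cell_volume("3DW-P-ZP", p) # 18
#' unit_cell_volume("3DW-O-ZO", p) # 27
#' @export
unit_cell_volume <- function(arch, p) {
  prod(unit_cell_dims(arch, p))
}

#' Unit-cell box dimensions
#'
#' @inheritParams unit_cell_volume
#' @return Named numeric vector `c(thickness, width, length)` in mm.
#' @export
unit_cell_dims <- function(arch, p) {
  arch <- as_architecture(arch)
  stopifnot(inherits(p, "unit_cell_params"))
  width <- if (arch$code == "3DW-O-ZO") {
    p$N * p$d_w + (p$N + 1) * p$d_f
  } else {
    p$N * p$d_w + p$N * p$d_f
  }
  c(thickness = p$M * p$d_w + (p$M + 1) * p$d_z,
    width = width,
    length = p$T * p$d_f + (p$T + 1) * p$d_z)
}

# Directional yarn volumes (mm^3) of the closed-form unit-cell model.
# Numerators follow the printed model formulas: each is
# (yarn count) x (path length) x (1 + crimp, where the model includes it)
# x (pi d^2 / 4). The semi-interlaced z-yarn term carries no crimp factor
# unless semi_z_crimp = "apply"; the orthogonal family carries none at all.
analytic_yarn_volumes <- function(arch, p, semi_z_crimp = c("verbatim", "apply")) {
  arch <- as_architecture(arch)
  semi_z_crimp <- match.arg(semi_z_crimp)
  area <- function(d) pi * d^2 / 4
  N <- p$N; M <- p$M; T <- p$T
  if (arch$code == "3DW-O-ZO") {
    V_w <- N * M * (T * p$d_f + (T + 1) * p$d_z) * area(p$d_w)
    V_f <- T * (N + 1) * (M * p$d_w + M * p$d_z) * area(p$d_f)
    V_z <- T * M * (N * p$d_w + (N + 1) * p$d_f + p$d_z) * area(p$d_z)
  } else {
    V_w <- N * M * (T * p$d_f + (T + 1) * p$d_z) * (1 + p$C_w) * area(p$d_w)
    V_f <- T * N * (M * p$d_w + M * p$d_z) * (1 + p$C_f) * area(p$d_f)
    z_crimp <- if (arch$code == "3DW-P-ZP" ||
                   (arch$code == "3DW-P-ZO" && semi_z_crimp == "apply")) {
      1 + p$C_z
    } else {
      1
    }
    V_z <- T * M * (N * p$d_w + N * p$d_f + p$d_z) * z_crimp * area(p$d_z)
  }
  c(V_w = V_w, V_f = V_f, V_z = V_z)
}

#' Analytical directional fiber fractions of a woven unit cell
#'
#' Evaluates the closed-form unit-cell model for the selected architecture:
#' directional yarn volumes (yarn count x path length x crimp factor x
#' circular cross-section area) divided by the unit-cell volume of
#' [unit_cell_volume()], expressed in percent. The total is the sum of the
#' three directional fractions and the total porosity its complement.
#'
#' Model conventions:
#' * plain (`3DW-P-ZP`): all three yarn systems carry their `(1 + C)` crimp
#'   factor;
#' * semi-interlaced (`3DW-P-ZO`): warp and filling carry crimp, the
#'   straight z-yarn does not (set `semi_z_crimp = "apply"` to include it);
#' * orthogonal (`3DW-O-ZO`): no crimp factors.
#'
#' Out-of-range geometries (total fiber fraction above 100%) are reported
#' with a warning and a `non_physical` flag rather than an error.
#'
#' @inheritParams unit_cell_volume
#' @param semi_z_crimp `"verbatim"` (default) leaves the semi-interlaced
#'   z-yarn term without a crimp factor, as in the model formulas;
#'   `"apply"` multiplies it by `(1 + C_z)`.
#' @return A [fraction_set()] with `source = "analytical"`.
#' @examples
#' p <- unit_cell_params(1, 1, 1, 1, 1, 1)
#' analytical_fractions("3DW-P-ZP", p)$V_fw # (3 pi / 4) / 18 * 100
#' @export
analytical_fractions <- function(arch, p, semi_z_crimp = c("verbatim", "apply")) {
  arch <- as_architecture(arch)
  semi_z_crimp <- match.arg(semi_z_crimp)
  vols <- analytic_yarn_volumes(arch, p, semi_z_crimp)
  V_p <- unit_cell_volume(arch, p)
  fr <- 100 * vols / V_p
  fraction_set(fr[["V_w"]], fr[["V_f"]], fr[["V_z"]],
               source = "analytical", arch = arch$code)
}
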
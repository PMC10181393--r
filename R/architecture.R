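#' Preform weave architectures
#'
#' The three 3D weave architectures differ in where yarn systems interlace:
#'
#' * `"3DW-P-ZP"` (plain): warp-filling and warp-z interlaced (plain 1/1),
#'   in-plane and through the thickness.
#' * `"3DW-P-ZO"` (semi-interlaced): warp-filling interlaced in-plane,
#'   z-yarns inserted straight (orthogonally).
#' * `"3DW-O-ZO"` (orthogonal): all three yarn systems straight; crossings
#'   occur only at the preform surfaces.
#'
#' @param code Architecture code, one of `"3DW-P-ZP"`, `"3DW-P-ZO"`,
#'   `"3DW-O-ZO"` (or the short forms `"plain"`, `"semi"`, `"orthogonal"`).
#' @return An object of class `preform_architecture` with fields `code`,
#'   `in_plane_interlaced` and `z_interlaced`.
#' @examples
#' preform_architecture("3DW-O-ZO")
#' @export
preform_architecture <- function(code) {
  short <- c(plain = "3DW-P-ZP", semi = "3DW-P-ZO", orthogonal = "3DW-O-ZO")
  if (code %in% names(short)) code <- short[[code]]
  code <- match.arg(code, c("3DW-P-ZP", "3DW-P-ZO", "3DW-O-ZO"))
  structure(
    list(
      code = code,
      in_plane_interlaced = code %in% c("3DW-P-ZP", "3DW-P-ZO"),
      z_interlaced = code == "3DW-P-ZP"
    ),
    class = "preform_architecture"
  )
}

#' @export
print.preform_architecture <- function(x, ...) {
  kind <- if (x$z_interlaced) "plain (fully interlaced)"
          else if (x$in_plane_interlaced) "semi-interlaced"
          else "orthogonal"
  cat(sprintf("<preform_architecture> %s: %s\n", x$code, kind))
  invisible(x)
}

as_architecture <- function(arch) {
  if (inherits(arch, "preform_architecture")) arch
  else preform_architecture(arch)
}

#' Unit-cell parameters of a 3D woven preform
#'
#' Defines the repeating box of the weave. `N` warp yarns per row, `M` warp
#' yarns per column and `T` weft (filling) positions per cell, together with
#' the three yarn diameters and crimps, fix the cell dimensions and yarn
#' inventory used by both the analytical and the voxel unit-cell models.
#'
#' Crimp is the fractional excess of a yarn's unstretched path length over
#' the cell span it crosses; a crimp entered here as `0.10` corresponds to a
#' reported crimp ratio of 10%.
#'
#' @param N Warp yarns per row (integer >= 1).
#' @param M Warp yarns per column (integer >= 1).
#' @param T Weft density number in the unit cell (integer >= 1).
#' @param d_w,d_f,d_z Warp / filling / z-yarn diameters in mm.
#' @param C_w,C_f,C_z Dimensionless crimp fractions (>= 0).
#' @return An object of class `unit_cell_params`.
#' @examples
#' unit_cell_params(N = 2, M = 2, T = 2, d_w = 0.504, d_f = 0.504,
#'                  d_z = 0.504, C_w = 0.0555, C_f = 0.1428, C_z = 0.50)
#' @export
unit_cell_params <- function(N, M, T, d_w, d_f, d_z,
                             C_w = 0, C_f = 0, C_z = 0) {
  counts <- c(N = N, M = M, T = T)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("N, M and T must be integers >= 1")
  }
  d <- c(d_w = d_w, d_f = d_f, d_z = d_z)
  if (any(!is.finite(d)) || any(d <= 0)) stop("yarn diameters must be > 0")
  cr <- c(C_w = C_w, C_f = C_f, C_z = C_z)
  if (any(!is.finite(cr)) || any(cr < 0)) stop("crimps must be >= 0")
  structure(
    list(N = as.integer(N), M = as.integer(M), T = as.integer(T),
         d_w = d_w, d_f = d_f, d_z = d_z,
         C_w = C_w, C_f = C_f, C_z = C_z),
    class = "unit_cell_params"
  )
}

#' @export
print.unit_cell_params <- function(x, ...) {
  cat(sprintf(
    "<unit_cell_params> N=%d M=%d T=%d  d(w,f,z)=(%.3f, %.3f, %.3f) mm  crimp(w,f,z)=(%.3g, %.3g, %.3g)\n",
    x$N, x$M, x$T, x$d_w, x$d_f, x$d_z, x$C_w, x$C_f, x$C_z
  ))
  invisible(x)
}

#' Default study unit-cell parameters for an architecture
#'
#' Convenience constructor: a 2 x 2 x 2 repeat cell with all three yarn
#' diameters derived from the bundled PGA yarn constants (311 tex plied
#' yarn, 1.56 g/cm^3, packing fraction 1 -> 0.504 mm) and the architecture's
#' reference crimp ratios.
#'
#' @param arch Architecture code or [preform_architecture()].
#' @param packing_fraction Packing fraction passed to
#'   [effective_yarn_diameter()].
#' @return A [unit_cell_params()] object.
#' @export
default_cell_params <- function(arch, packing_fraction = 1) {
  arch <- as_architecture(arch)
  d <- effective_yarn_diameter(311, packing_fraction, fiber_density = 1.56)
  crimps <- switch(arch$code,
    "3DW-P-ZP" = c(0.0555, 0.1428, 0.5000),
    "3DW-P-ZO" = c(0.0344, 0.1111, 0.3333),
    "3DW-O-ZO" = c(0.0200, 0.0714, 0.1006)
  )
  unit_cell_params(N = 2, M = 2, T = 2, d_w = d, d_f = d, d_z = d,
                   C_w = crimps[1], C_f = crimps[2], C_z = crimps[3])
}
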
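#' Yarn specification
#'
#' Describes a plied multifilament yarn by its filament diameter, ply count,
#' linear density and fiber mass density. The effective (circular) yarn
#' diameter can be supplied directly or derived from the linear density via
#' [effective_yarn_diameter()].
#'
#' @param filament_diameter Filament diameter in micrometres.
#' @param ply_count Number of plied single yarns.
#' @param linear_density Yarn linear density in tex (g/km) of the plied yarn.
#' @param fiber_density Fiber mass density in g/cm^3.
#' @param effective_diameter Optional effective yarn diameter in mm. When
#'   `NULL` it is derived from `linear_density`, `fiber_density` and
#'   `packing_fraction`.
#' @param packing_fraction Fiber packing fraction inside the yarn envelope,
#'   in (0, 1]. Only used when `effective_diameter` is derived.
#'
#' @return An object of class `yarn_spec`.
#' @examples
#' y <- yarn_spec(13.7, 50, 311, 1.56)
#' y$effective_diameter  # ~0.504 mm
#' @export
yarn_spec <- function(filament_diameter, ply_count, linear_density,
                      fiber_density, effective_diameter = NULL,
                      packing_fraction = 1) {
  stopifnot(
    is.numeric(filament_diameter), filament_diameter > 0,
    is.numeric(ply_count), ply_count >= 1,
    is.numeric(linear_density), linear_density > 0,
    is.numeric(fiber_density), fiber_density > 0
  )
  spec <- structure(
    list(
      filament_diameter = filament_diameter,
      ply_count = as.integer(ply_count),
      linear_density = linear_density,
      fiber_density = fiber_density,
      packing_fraction = packing_fraction,
      effective_diameter = effective_diameter
    ),
    class = "yarn_spec"
  )
  if (is.null(effective_diameter)) {
    spec$effective_diameter <- effective_yarn_diameter(spec, packing_fraction)
  }
  if (spec$effective_diameter <= filament_diameter / 1000) {
    stop("effective yarn diameter must exceed the filament diameter")
  }
  spec
}

#' @export
print.yarn_spec <- function(x, ...) {
  cat(sprintf(
    "<yarn_spec> %g tex x %d ply, fiber %.3g g/cm^3, d_eff %.3f mm\n",
    x$linear_density, x$ply_count, x$fiber_density, x$effective_diameter
  ))
  invisible(x)
}

#' Effective circular yarn diameter from linear density
#'
#' Inverts the mass balance of an idealized circular yarn: a yarn of linear
#' density `T` tex made of fiber with density `rho` g/cm^3 packed at
#' fraction `phi` has cross-sectional envelope area
#' `A = T / (1000 rho phi)` mm^2 and effective diameter
#' `d = sqrt(4 A / pi)` mm. With `phi = 1` the yarn envelope holds exactly
#' its fiber volume; smaller packing fractions inflate the envelope.
#'
#' @param spec A [yarn_spec()], or a numeric linear density in tex.
#' @param packing_fraction Packing fraction in (0, 1].
#' @param fiber_density Fiber density in g/cm^3; only used when `spec` is
#'   numeric.
#' @return Effective yarn diameter in mm.
#' @examples
#' effective_yarn_diameter(311, 1, fiber_density = 1.56)   # 0.504 mm
#' effective_yarn_diameter(311, 0.5, fiber_density = 1.56) # x sqrt(2)
#' @export
effective_yarn_diameter <- function(spec, packing_fraction = 1,
                                    fiber_density = NULL) {
  if (inherits(spec, "yarn_spec")) {
    tex <- spec$linear_density
    rho <- spec$fiber_density
  } else {
    tex <- spec
    rho <- fiber_density
    if (is.null(rho)) stop("fiber_density is required for a numeric spec")
  }
  if (!is.numeric(tex) || tex <= 0 || !is.numeric(rho) || rho <= 0) {
    stop("linear density and fiber density must be positive")
  }
  if (!is.numeric(packing_fraction) || packing_fraction <= 0 ||
      packing_fraction > 1) {
    stop("packing_fraction must lie in (0, 1]")
  }
  # tex g/km -> g/mm: 1e-6; rho g/cm^3 -> g/mm^3: 1e-3
  area <- (tex * 1e-6) / (rho * 1e-3 * packing_fraction) # mm^2
  sqrt(4 * area / pi)
}
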
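#' Constituent material properties
#'
#' Elastic and strength constants of one scaffold phase (reinforcing fiber
#' or hydrogel matrix). The shear modulus defaults to the isotropic relation
#' `G = E / (2 (1 + nu))` when not supplied.
#'
#' @param E Tensile modulus in GPa.
#' @param sigma Tensile strength in MPa.
#' @param nu Poisson ratio (0 <= nu < 0.5).
#' @param G Shear modulus in GPa; derived isotropically when `NULL`.
#' @param role `"fiber"` or `"matrix"`.
#' @return Object of class `material_props`.
#' @examples
#' pga_fiber()
#' hydrogel_matrix()
#' @export
material_props <- function(E, sigma, nu, G = NULL,
                           role = c("fiber", "matrix")) {
  role <- match.arg(role)
  stopifnot(is.numeric(E), E > 0, is.numeric(sigma), sigma >= 0,
            is.numeric(nu), nu >= 0, nu < 0.5)
  if (is.null(G)) G <- isotropic_shear_modulus(E, nu)
  structure(list(E = E, G = G, nu = nu, sigma = sigma, role = role),
            class = "material_props")
}

#' @export
print.material_props <- function(x, ...) {
  cat(sprintf(
    "<material_props> %s: E %.4g GPa, G %.4g GPa, nu %.3g, sigma %.4g MPa\n",
    x$role, x$E, x$G, x$nu, x$sigma
  ))
  invisible(x)
}

#' Default PGA fiber constants
#'
#' Average tensile modulus 6.5 GPa, tensile strength 79.85 MPa, Poisson
#' ratio 0.35.
#' @return A [material_props()] object with `role = "fiber"`.
#' @export
pga_fiber <- function() material_props(E = 6.5, sigma = 79.85, nu = 0.35,
                                       role = "fiber")

#' Default hydrogel matrix constants
#'
#' Average tensile modulus 75e-6 GPa, tensile strength 25e-3 MPa, Poisson
#' ratio 0.457. Mechanically negligible next to the fiber, but kept in all
#' rule-of-mixtures terms.
#' @return A [material_props()] object with `role = "matrix"`.
#' @export
hydrogel_matrix <- function() material_props(E = 75e-6, sigma = 25e-3,
                                             nu = 0.457, role = "matrix")

#' Read material constants from a YAML file
#'
#' Expects top-level `fiber` and `matrix` blocks with keys `E_GPa`,
#' `sigma_MPa`, `nu` and optional `G_GPa`.
#'
#' @param path Path to a YAML file.
#' @return List with elements `fiber` and `matrix`, both [material_props()].
#' @export
read_materials <- function(path) {
  cfg <- yaml::read_yaml(path)
  parse_block <- function(b, role) {
    material_props(E = b$E_GPa, sigma = b$sigma_MPa, nu = b$nu,
                   G = b$G_GPa, role = role)
  }
  list(fiber = parse_block(cfg$fiber, "fiber"),
       matrix = parse_block(cfg$matrix, "matrix"))
}

#' Linear rule of mixtures
#'
#' Volume-weighted combination of a fiber and a matrix property:
#' `P = P_f V_f + P_m (1 - V_f)`. The same linear form serves tensile
#' modulus, shear modulus, Poisson ratio and tensile strength.
#'
#' @param prop_fiber,prop_matrix Constituent property values (same unit).
#' @param V_f Fiber volume fraction as a fraction in \[0, 1\].
#' @return The mixed property.
#' @examples
#' rule_of_mixtures(6.5, 75e-6, 0.4933) # ~3.21 GPa
#' @export
rule_of_mixtures <- function(prop_fiber, prop_matrix, V_f) {
  if (!is.numeric(V_f) || any(V_f < 0) || any(V_f > 1)) {
    stop("V_f must lie in [0, 1]")
  }
  prop_fiber * V_f + prop_matrix * (1 - V_f)
}

#' Isotropic shear modulus from tensile modulus and Poisson ratio
#'
#' `G = E / (2 (1 + nu))`.
#'
#' @param E Tensile modulus (any unit; result in the same unit).
#' @param nu Poisson ratio, > -1.
#' @return Shear modulus.
#' @examples
#' isotropic_shear_modulus(6.5, 0.35) # 2.4074
#' @export
isotropic_shear_modulus <- function(E, nu) {
  stopifnot(is.numeric(E), all(E >= 0), is.numeric(nu), all(nu > -1))
  E / (2 * (1 + nu))
}

#' Rule-of-mixtures scaffold mechanics from a fraction set
#'
#' Predicts total and directional tensile modulus, shear modulus, Poisson
#' ratio and tensile strength of a fiber-preform/hydrogel scaffold. Totals
#' use the total fiber fraction `V_fp`; each directional property uses its
#' own directional fiber fraction with the matrix taking the full
#' complement `1 - V_dir` (the hydrogel is assumed to fill all space not
#' occupied by that yarn direction). Index convention: 1 = warp,
#' 2 = filling, 3 = z-yarn; `E_11` is the warp-direction modulus, `G_12`
#' the warp-filling shear modulus, and so on.
#'
#' @param fractions A [fraction_set()] (percent scale).
#' @param fiber,matrix [material_props()] for the two phases; default PGA
#'   fiber and hydrogel matrix.
#' @return Object of class `mechanical_result`: named list with moduli
#'   `E_11`, `E_22`, `E_33`, `E_p` (GPa), shear moduli `G_12`, `G_23`,
#'   `G_13`, `G_p` (GPa), Poisson ratios `nu_12`, `nu_23`, `nu_13`, `nu_p`,
#'   and strengths `sigma_11`, `sigma_22`, `sigma_33`, `sigma_ps` (MPa).
#' @examples
#' fr <- fraction_set(20.06, 7.03, 9.55)
#' scaffold_mechanics(fr)$E_p # ~2.38 GPa
#' @export
scaffold_mechanics <- function(fractions, fiber = pga_fiber(),
                               matrix = hydrogel_matrix()) {
  stopifnot(inherits(fractions, "fraction_set"),
            inherits(fiber, "material_props"),
            inherits(matrix, "material_props"))
  v <- c(fractions$V_fw, fractions$V_ff, fractions$V_fz, fractions$V_fp) / 100
  mix <- function(pf, pm) rule_of_mixtures(pf, pm, v)
  E <- mix(fiber$E, matrix$E)
  G <- mix(fiber$G, matrix$G)
  nu <- mix(fiber$nu, matrix$nu)
  s <- mix(fiber$sigma, matrix$sigma)
  structure(
    list(E_11 = E[1], E_22 = E[2], E_33 = E[3], E_p = E[4],
         G_12 = G[1], G_23 = G[2], G_13 = G[3], G_p = G[4],
         nu_12 = nu[1], nu_23 = nu[2], nu_13 = nu[3], nu_p = nu[4],
         sigma_11 = s[1], sigma_22 = s[2], sigma_33 = s[3], sigma_ps = s[4]),
    arch = attr(fractions, "arch"), source = attr(fractions, "source"),
    class = "mechanical_result"
  )
}

#' @export
print.mechanical_result <- function(x, digits = 2, ...) {
  cat("<mechanical_result>",
      attr(x, "arch") %||% "", attr(x, "source") %||% "", "\n")
  cat(sprintf("  E (GPa):     11 %.2f  22 %.2f  33 %.2f  total %.2f\n",
              x$E_11, x$E_22, x$E_33, x$E_p))
  cat(sprintf("  G (GPa):     12 %.2f  23 %.2f  13 %.2f  total %.2f\n",
              x$G_12, x$G_23, x$G_13, x$G_p))
  cat(sprintf("  nu:          12 %.2f  23 %.2f  13 %.2f  total %.2f\n",
              x$nu_12, x$nu_23, x$nu_13, x$nu_p))
  cat(sprintf("  sigma (MPa): 11 %.2f  22 %.2f  33 %.2f  total %.2f\n",
              x$sigma_11, x$sigma_22, x$sigma_33, x$sigma_ps))
  invisible(x)
}

#' @export
as.data.frame.mechanical_result <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(
    arch = attr(x, "arch") %||% NA_character_,
    source = attr(x, "source") %||% NA_character_,
    as.data.frame(unclass(x), stringsAsFactors = FALSE),
    stringsAsFactors = FALSE, row.names = row.names
  )
}
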
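#' Bundled reference data for three PGA preform architectures
#'
#' The package ships the bench characterization of three 3D woven
#' polyglycolic-acid preforms (plain `3DW-P-ZP`, semi-interlaced
#' `3DW-P-ZO`, orthogonal `3DW-O-ZO`) as plain-text tables under
#' `inst/extdata`:
#'
#' * `"measurements"`: structure dimensions, uncrimped yarn lengths, z-arc
#'   lengths and bulk density per architecture, plus the reported crimp
#'   central values (`C_w_ref`, `C_f_ref`, `C_z_ref`, percent).
#' * `"fractions"`: directional and total fiber-volume and porosity
#'   fractions per architecture and source (`measured`, `analytical`,
#'   `numerical`).
#' * `"mechanics"`: rule-of-mixtures stiffness/strength results per
#'   architecture and source.
#' * `"materials"`: fiber and hydrogel constants (parsed, as
#'   [material_props()]).
#' * `"yarn"`: PGA filament/yarn constants (list).
#'
#' @param type One of `"measurements"`, `"fractions"`, `"mechanics"`,
#'   `"materials"`, `"yarn"`.
#' @return A data.frame, or a list for `"materials"`/`"yarn"`.
#' @examples
#' head(pga_reference("fractions"))
#' @export
pga_reference <- function(type = c("measurements", "fractions", "mechanics",
                                   "materials", "yarn")) {
  type <- match.arg(type)
  path <- function(f) system.file("extdata", f, package = "wovencell",
                                  mustWork = TRUE)
  switch(type,
    measurements = utils::read.csv(path("pga_preform_measurements.csv"),
                                   stringsAsFactors = FALSE),
    fractions = utils::read.csv(path("pga_reference_fractions.csv"),
                                stringsAsFactors = FALSE),
    mechanics = utils::read.csv(path("pga_reference_mechanics.csv"),
                                stringsAsFactors = FALSE),
    materials = read_materials(path("materials.yaml")),
    yarn = yaml::read_yaml(path("pga_yarn.yaml"))
  )
}

#' Reference fraction sets as fraction_set objects
#'
#' Convenience wrapper around `pga_reference("fractions")`: returns the
#' fraction block for one architecture/source pair as a [fraction_set()].
#' The measured and numerical blocks carry independently determined totals,
#' so their directional fractions need not sum to the total (the object is
#' marked non-additive in that case).
#'
#' @param arch Architecture code.
#' @param source `"measured"`, `"analytical"` or `"numerical"`.
#' @return A [fraction_set()].
#' @export
reference_fraction_set <- function(arch,
                                   source = c("measured", "analytical",
                                              "numerical")) {
  source <- match.arg(source)
  tab <- pga_reference("fractions")
  row <- tab[tab$code == arch & tab$source == source, ]
  if (nrow(row) != 1) stop("no reference block for ", arch, " / ", source)
  fraction_set(row$V_fw, row$V_ff, row$V_fz, V_fp = row$V_fp,
               source = source, arch = arch)
}
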
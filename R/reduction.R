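#' Yarn crimp ratio in percent
#'
#' Crimp is the fractional excess of the uncrimped (straightened) yarn
#' length over the structure dimension the yarn spans:
#' `C = 100 (l - S) / S`.
#'
#' @param uncrimped_length Straightened yarn length `l` in mm.
#' @param structure_dimension Structure dimension `S` spanned by the yarn,
#'   in mm; must be positive.
#' @return Crimp in percent. A negative crimp (yarn shorter than the span it
#'   crosses, a measurement artifact) is returned with a warning, not an
#'   error, so noisy batch reductions never abort.
#' @examples
#' crimp_percent(51, 50)  # 2
#' crimp_percent(15, 10)  # 50
#' @export
crimp_percent <- function(uncrimped_length, structure_dimension) {
  if (!is.numeric(structure_dimension) || any(structure_dimension <= 0)) {
    stop("structure_dimension must be positive")
  }
  if (!is.numeric(uncrimped_length) || any(uncrimped_length <= 0)) {
    stop("uncrimped_length must be positive")
  }
  crimp <- 100 * (uncrimped_length - structure_dimension) / structure_dimension
  if (any(crimp < 0)) {
    warning("negative crimp: uncrimped length below the structure dimension")
  }
  crimp
}

#' Measured total fiber volume fraction from bulk density
#'
#' `V_fp = 100 rho_p / rho_f`: the preform bulk density over the fiber
#' density, in percent.
#'
#' @param rho_p Preform bulk density in g/cm^3.
#' @param rho_f Fiber density in g/cm^3.
#' @return Total fiber volume fraction in percent.
#' @examples
#' measured_total_fraction(0.74, 1.50) # 49.33
#' @export
measured_total_fraction <- function(rho_p, rho_f) {
  if (!is.numeric(rho_p) || any(rho_p <= 0) ||
      !is.numeric(rho_f) || any(rho_f <= 0)) {
    stop("densities must be positive")
  }
  if (any(rho_p > rho_f)) {
    stop("rho_p exceeds rho_f: fiber fraction would exceed 100%")
  }
  100 * rho_p / rho_f
}

#' Directional fiber fraction from a directional mass share
#'
#' `V_dir = (M_dir / M_p * 100) * rho_p / rho_f`: the mass share of one yarn
#' direction scaled by the measured total fraction. When the directional
#' masses sum to the preform mass, the three directional fractions sum to
#' [measured_total_fraction()].
#'
#' @param M_dir Mass of the yarn direction in g.
#' @param M_p Total preform mass in g.
#' @param rho_p Preform bulk density in g/cm^3.
#' @param rho_f Fiber density in g/cm^3.
#' @return Directional fiber volume fraction in percent.
#' @export
directional_fraction_from_mass <- function(M_dir, M_p, rho_p, rho_f) {
  if (!is.numeric(M_dir) || any(M_dir <= 0) ||
      !is.numeric(M_p) || any(M_p <= 0)) {
    stop("masses must be positive")
  }
  if (any(M_dir > M_p)) stop("directional mass exceeds the preform mass")
  (M_dir / M_p * 100) * rho_p / rho_f
}

# required columns of the measurement CSV dialect
measurement_columns <- c(
  "preform_code", "S_l", "S_w", "S_t", "l_w", "l_f", "l_zt",
  "M_w", "M_f", "M_z", "M_p", "rho_p"
)

#' Read a preform measurement table
#'
#' One row per preform; values in mm, g and g/cm^3. Required columns:
#' `preform_code`, structure dimensions `S_l`, `S_w`, `S_t`, uncrimped yarn
#' lengths `l_w`, `l_f`, `l_zt`, directional and total masses `M_w`, `M_f`,
#' `M_z`, `M_p`, and bulk density `rho_p`. Additional columns (e.g. the
#' descriptive z-arc lengths `l_za`, `l_z`, spacings, yarn densities or
#' angles, or `true_*` ground-truth sidecars from the synthetic generator)
#' pass through untouched.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of measurements.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_measurements(df)
  df
}

#' @rdname read_measurements
#' @param df Measurement data.frame.
#' @export
write_measurements <- function(df, path) {
  validate_measurements(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_measurements <- function(df) {
  missing <- setdiff(measurement_columns, names(df))
  if (length(missing)) {
    stop("missing measurement columns: ", paste(missing, collapse = ", "))
  }
  num <- setdiff(measurement_columns, "preform_code")
  for (col in num) {
    if (!is.numeric(df[[col]])) stop("column ", col, " must be numeric")
  }
  bad <- with(df, M_w + M_f + M_z > M_p + 1e-6)
  if (any(bad)) {
    stop("directional masses exceed the preform mass (tolerance 1e-6 g) in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  invisible(df)
}

#' Reduce raw preform measurements to crimps and fractions
#'
#' Applies the crimp ratio to the three length/span pairs and the
#' density/mass relations to obtain the measured directional and total
#' fiber-volume and porosity fractions, one row per preform.
#'
#' @param df Measurement data.frame in the dialect of
#'   [read_measurements()].
#' @param rho_f Fiber density in g/cm^3 (default PGA, 1.50).
#' @return A data.frame with columns `preform_code`, `C_w`, `C_f`, `C_z`
#'   (percent), `V_fw`, `V_ff`, `V_fz`, `V_fp`, `V_wpr`, `V_fpr`, `V_zpr`,
#'   `V_tpr` (percent).
#' @export
reduce_measurements <- function(df, rho_f = 1.50) {
  validate_measurements(df)
  V_fw <- directional_fraction_from_mass(df$M_w, df$M_p, df$rho_p, rho_f)
  V_ff <- directional_fraction_from_mass(df$M_f, df$M_p, df$rho_p, rho_f)
  V_fz <- directional_fraction_from_mass(df$M_z, df$M_p, df$rho_p, rho_f)
  V_fp <- measured_total_fraction(df$rho_p, rho_f)
  V_tpr <- porosity_complement(V_fp)
  data.frame(
    preform_code = df$preform_code,
    C_w = crimp_percent(df$l_w, df$S_l),
    C_f = crimp_percent(df$l_f, df$S_w),
    C_z = crimp_percent(df$l_zt, df$S_t),
    V_fw = V_fw, V_ff = V_ff, V_fz = V_fz, V_fp = V_fp,
    V_wpr = V_tpr / 3, V_fpr = V_tpr / 3, V_zpr = V_tpr / 3, V_tpr = V_tpr,
    stringsAsFactors = FALSE
  )
}
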
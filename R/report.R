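#' Pairwise relative differences between two fraction sets
#'
#' Computes `100 (a - b) / b` per field — by convention model minus
#' measured over measured, so a positive value means the model over-predicts.
#' Fields where `b` is zero are returned as `NA`.
#'
#' @param a,b [fraction_set()] objects (same preform; `a` is usually a
#'   model, `b` the measurement).
#' @return Named numeric vector of relative differences in percent over the
#'   fields `V_fw`, `V_ff`, `V_fz`, `V_fp`, `V_wpr`, `V_fpr`, `V_zpr`,
#'   `V_tpr`.
#' @examples
#' a <- fraction_set(17.23, 14.96, 21.33, V_fp = 53.52)
#' b <- fraction_set(24.87, 14.15, 9.96, V_fp = 49.33)
#' compare_sources(a, b)[["V_fp"]] # +8.49
#' @export
compare_sources <- function(a, b) {
  stopifnot(inherits(a, "fraction_set"), inherits(b, "fraction_set"))
  fields <- c("V_fw", "V_ff", "V_fz", "V_fp", "V_wpr", "V_fpr", "V_zpr", "V_tpr")
  av <- vapply(fields, function(f) a[[f]], 0)
  bv <- vapply(fields, function(f) b[[f]], 0)
  out <- ifelse(bv == 0, NA_real_, 100 * (av - bv) / bv)
  names(out) <- fields
  out
}

#' Run the full preform comparison pipeline
#'
#' Orchestrates, for each configured preform: the measured fraction source
#' (direct fractions, directional masses, a measurement CSV, or the
#' synthetic generator), the analytical unit-cell model, optionally the
#' voxel unit-cell model, then rule-of-mixtures mechanics for every source
#' and relative differences of each model against the measurement.
#'
#' The configuration is a YAML file or an equivalent nested list:
#' ```yaml
#' rho_f: 1.50
#' voxel: {enabled: false, resolution: 40, cross_section: circle}
#' materials: null            # path to a materials YAML; default constants
#' preforms:
#'   - code: 3DW-P-ZP
#'     params: {N: 2, M: 2, T: 2, packing_fraction: 1.0,
#'              C_w: 0.0555, C_f: 0.1428, C_z: 0.50,
#'              semi_z_crimp: verbatim}   # d_w/d_f/d_z override the derived d
#'     measured: {rho_p: 0.74, V_fw: 24.87, V_ff: 14.15, V_fz: 9.96}
#' ```
#' Alternative `measured` blocks: `{csv: path}` (rows for this code are
#' reduced and averaged), `{M_w: ..., M_f: ..., M_z: ..., rho_p: ...}`
#' (mass split), or `{synthetic: {replicates: ..., seed: ...}}`.
#'
#' @param config Path to a YAML config, or a list with the same structure.
#' @param out Optional output directory; when given, writes
#'   `fractions.csv`, `mechanics.csv`, `differences.csv` (2-decimal
#'   presentation rounding) and `summary.json` (full precision).
#' @param verbose Emit progress messages (to stderr).
#' @return An object of class `comparison_report`: list with data.frames
#'   `fractions`, `mechanics`, `differences`.
#' @export
run_pipeline <- function(config, out = NULL, verbose = TRUE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  say <- function(...) if (verbose) message(...)
  rho_f <- cfg$rho_f %||% 1.50
  mats <- if (!is.null(cfg$materials)) read_materials(cfg$materials)
          else list(fiber = pga_fiber(), matrix = hydrogel_matrix())
  vox_cfg <- cfg$voxel %||% list(enabled = FALSE)

  frac_rows <- list(); mech_rows <- list(); diff_rows <- list()
  for (pf in cfg$preforms %||% list()) {
    code <- pf$code %||% stop("preform block without a code")
    arch <- as_architecture(pf$arch %||% code)
    say("preform ", code, ": reducing measured source")
    measured <- measured_fractions_from_config(pf$measured, arch, rho_f)
    params <- params_from_config(pf$params, arch)
    say("preform ", code, ": analytical unit cell (N=", params$N,
        " M=", params$M, " T=", params$T, ")")
    semi_z <- (pf$params %||% list())$semi_z_crimp %||% "verbatim"
    analytical <- analytical_fractions(arch, params, semi_z_crimp = semi_z)
    sources <- list(measured = measured, analytical = analytical)
    if (isTRUE(vox_cfg$enabled)) {
      res <- vox_cfg$resolution %||% 40
      say("preform ", code, ": voxel unit cell at ", res, " voxels/mm")
      cell <- build_unit_cell(arch, params, resolution = res,
                              cross_section = vox_cfg$cross_section %||% "circle")
      sources$voxel <- voxel_fractions(cell)
    }
    for (src in names(sources)) {
      fs <- sources[[src]]
      attr(fs, "source") <- src
      attr(fs, "arch") <- code
      frac_rows[[length(frac_rows) + 1L]] <- as.data.frame(fs)
      mech_rows[[length(mech_rows) + 1L]] <-
        as.data.frame(scaffold_mechanics(fs, mats$fiber, mats$matrix))
      if (src != "measured" && !is.null(measured)) {
        d <- compare_sources(fs, measured)
        diff_rows[[length(diff_rows) + 1L]] <- data.frame(
          arch = code, source = src, t(d),
          stringsAsFactors = FALSE
        )
      }
    }
  }

  report <- structure(
    list(
      fractions = rbind_or_empty(frac_rows),
      mechanics = rbind_or_empty(mech_rows),
      differences = rbind_or_empty(diff_rows)
    ),
    class = "comparison_report"
  )
  if (!is.null(out)) write_report(report, out, verbose = verbose)
  report
}

rbind_or_empty <- function(rows) {
  if (length(rows)) do.call(rbind, rows) else data.frame()
}

params_from_config <- function(p, arch) {
  p <- p %||% list()
  if (is.null(p$d_w) || is.null(p$d_f) || is.null(p$d_z)) {
    d <- effective_yarn_diameter(p$tex %||% 311,
                                 p$packing_fraction %||% 1,
                                 fiber_density = p$yarn_density %||% 1.56)
  }
  defaults <- default_cell_params(arch)
  unit_cell_params(
    N = p$N %||% defaults$N, M = p$M %||% defaults$M, T = p$T %||% defaults$T,
    d_w = p$d_w %||% d, d_f = p$d_f %||% d, d_z = p$d_z %||% d,
    C_w = p$C_w %||% defaults$C_w,
    C_f = p$C_f %||% defaults$C_f,
    C_z = p$C_z %||% defaults$C_z
  )
}

measured_fractions_from_config <- function(m, arch, rho_f) {
  if (is.null(m)) return(NULL)
  if (!is.null(m$csv)) {
    df <- read_measurements(m$csv)
    df <- df[df$preform_code == arch$code | is.na(df$preform_code) |
               !nzchar(df$preform_code), , drop = FALSE]
    if (!nrow(df)) stop("no measurement rows for ", arch$code, " in ", m$csv)
    red <- suppressWarnings(reduce_measurements(df, rho_f = rho_f))
    return(fraction_set(mean(red$V_fw), mean(red$V_ff), mean(red$V_fz),
                        V_fp = mean(red$V_fp),
                        source = "measured", arch = arch$code))
  }
  if (!is.null(m$synthetic)) {
    s <- m$synthetic
    cfg <- synthetic_config(arch,
                            replicates = s$replicates %||% 10L,
                            seed = s$seed %||% 1L)
    red <- suppressWarnings(
      reduce_measurements(generate_measurements(cfg), rho_f = rho_f))
    return(fraction_set(mean(red$V_fw), mean(red$V_ff), mean(red$V_fz),
                        V_fp = mean(red$V_fp),
                        source = "measured", arch = arch$code))
  }
  if (!is.null(m$M_w)) {
    V_fw <- directional_fraction_from_mass(m$M_w, m$M_p, m$rho_p, rho_f)
    V_ff <- directional_fraction_from_mass(m$M_f, m$M_p, m$rho_p, rho_f)
    V_fz <- directional_fraction_from_mass(m$M_z, m$M_p, m$rho_p, rho_f)
    return(fraction_set(V_fw, V_ff, V_fz,
                        V_fp = measured_total_fraction(m$rho_p, rho_f),
                        source = "measured", arch = arch$code))
  }
  if (!is.null(m$V_fw)) {
    V_fp <- if (!is.null(m$rho_p)) measured_total_fraction(m$rho_p, rho_f)
            else m$V_fp %||% NULL
    return(fraction_set(m$V_fw, m$V_ff, m$V_fz, V_fp = V_fp,
                        source = "measured", arch = arch$code))
  }
  stop("measured block must supply csv, synthetic, masses or fractions")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", nrow(x$fractions), "fraction rows,",
      nrow(x$mechanics), "mechanics rows\n")
  if (nrow(x$fractions)) {
    df <- x$fractions
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, 2)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

write_report <- function(report, out, verbose = TRUE) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  round2 <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, 2)
    df
  }
  utils::write.csv(round2(report$fractions), file.path(out, "fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(round2(report$mechanics), file.path(out, "mechanics.csv"),
                   row.names = FALSE)
  utils::write.csv(round2(report$differences), file.path(out, "differences.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (verbose) message("report written to ", normalizePath(out))
  invisible(out)
}

#' Bar chart of fiber-volume fractions by source
#'
#' Grouped bars of the directional and total fiber fractions per
#' architecture and source, mirroring the usual measured/model comparison
#' figures. Requires ggplot2.
#'
#' @param report A [run_pipeline()] result.
#' @param what `"fractions"` (V_fw, V_ff, V_fz, V_fp) or `"porosity"`.
#' @return A ggplot object.
#' @export
plot_report <- function(report, what = c("fractions", "porosity")) {
  what <- match.arg(what)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_report requires the ggplot2 package")
  }
  df <- report$fractions
  cols <- if (what == "fractions") c("V_fw", "V_ff", "V_fz", "V_fp")
          else c("V_wpr", "V_fpr", "V_zpr", "V_tpr")
  long <- do.call(rbind, lapply(cols, function(cl) {
    data.frame(arch = df$arch, source = df$source, quantity = cl,
               value = df[[cl]], stringsAsFactors = FALSE)
  }))
  long$quantity <- factor(long$quantity, levels = cols)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$quantity, y = .data$value,
                               fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~arch) +
    ggplot2::labs(x = NULL, y = "fraction (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
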
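#' Configuration for the synthetic measurement generator
#'
#' Defines the ground truth and noise model for simulated preform
#' measurement tables. The defaults emulate the bundled study conditions:
#' per-architecture structure dimensions and crimp ratios from the
#' reference measurement table, yarn diameters from the PGA yarn constants,
#' and Gaussian additive noise with standard deviations set to the stated
#' instrument precisions (digital caliper 0.01 mm for structure dimensions,
#' flexible ruler 0.2 mm for yarn lengths, balance 0.0001 g for masses;
#' 0.01 g/cm^3 for bulk density).
#'
#' @param arch Architecture code or [preform_architecture()].
#' @param params [unit_cell_params()] giving the true repeat geometry;
#'   default [default_cell_params()] for the architecture (its crimps are
#'   the true crimps).
#' @param dims True structure length/width/thickness `c(S_l, S_w, S_t)` in
#'   mm; default the architecture's reference dimensions.
#' @param rho_f Fiber density in g/cm^3.
#' @param noise_sd_dim SD of structure-dimension noise, mm.
#' @param noise_sd_length SD of yarn-length noise, mm.
#' @param noise_sd_mass SD of mass noise, g.
#' @param noise_sd_density SD of bulk-density noise, g/cm^3.
#' @param replicates Number of simulated preforms (>= 1).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(arch, params = default_cell_params(arch),
                             dims = NULL, rho_f = 1.50,
                             noise_sd_dim = 0.01, noise_sd_length = 0.2,
                             noise_sd_mass = 1e-4, noise_sd_density = 0.01,
                             replicates = 1L, seed = 1L) {
  arch <- as_architecture(arch)
  stopifnot(inherits(params, "unit_cell_params"))
  if (is.null(dims)) {
    dims <- switch(arch$code,
      "3DW-O-ZO" = c(50, 28, 6.36),
      "3DW-P-ZO" = c(29, 18, 6.00),
      "3DW-P-ZP" = c(36, 23, 10.00)
    )
  }
  stopifnot(length(dims) == 3, all(dims > 0))
  sds <- c(noise_sd_dim, noise_sd_length, noise_sd_mass, noise_sd_density)
  if (any(sds < 0)) stop("noise SDs must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(
    list(arch = arch, params = params,
         dims = c(S_l = dims[1], S_w = dims[2], S_t = dims[3]),
         rho_f = rho_f,
         noise_sd_dim = noise_sd_dim, noise_sd_length = noise_sd_length,
         noise_sd_mass = noise_sd_mass, noise_sd_density = noise_sd_density,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate synthetic preform measurement records
#'
#' For each replicate the generator derives a fully self-consistent ground
#' truth — uncrimped lengths `l = S (1 + C)`, directional fiber volumes
#' from the architecture's analytical unit-cell fractions applied to the
#' structure volume, masses as fiber density times volume, and bulk density
#' as total mass over structure volume — then adds independent Gaussian
#' noise per quantity. With all noise SDs zero, [reduce_measurements()]
#' recovers the ground truth exactly.
#'
#' Draws that would make any length or mass non-positive are redrawn (with
#' a warning), capped at 100 attempts per replicate.
#'
#' @param cfg A [synthetic_config()].
#' @return A measurement data.frame in the dialect of
#'   [read_measurements()], with the ground truth carried in sidecar
#'   columns prefixed `true_` (ignored by the reduction reader).
#' @export
generate_measurements <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  p <- cfg$params
  fr <- analytical_fractions(cfg$arch, p)
  V_s <- prod(cfg$dims) # mm^3
  vol_dir <- c(fr$V_fw, fr$V_ff, fr$V_fz) / 100 * V_s # mm^3
  mass_dir <- cfg$rho_f * 1e-3 * vol_dir # g
  rho_p_true <- sum(mass_dir) / V_s * 1e3 # g/cm^3
  crimps <- c(p$C_w, p$C_f, p$C_z)
  l_true <- cfg$dims * (1 + crimps)

  one <- function(rep_id) {
    for (attempt in seq_len(100L)) {
      S <- cfg$dims + stats::rnorm(3, 0, cfg$noise_sd_dim)
      l <- l_true + stats::rnorm(3, 0, cfg$noise_sd_length)
      m <- mass_dir + stats::rnorm(3, 0, cfg$noise_sd_mass)
      rho_p <- rho_p_true + stats::rnorm(1, 0, cfg$noise_sd_density)
      l_z <- S[3]
      ok <- all(S > 0) && all(l > 0) && all(m > 0) && rho_p > 0 &&
        rho_p <= cfg$rho_f && l[3] >= l_z
      if (ok) {
        return(data.frame(
          preform_code = cfg$arch$code, replicate = rep_id,
          S_l = S[1], S_w = S[2], S_t = S[3],
          l_w = l[1], l_f = l[2], l_zt = l[3],
          l_za = l[3] - l_z, l_z = l_z,
          M_w = m[1], M_f = m[2], M_z = m[3], M_p = sum(m),
          rho_p = rho_p,
          true_C_w = 100 * crimps[1], true_C_f = 100 * crimps[2],
          true_C_z = 100 * crimps[3],
          true_V_fw = fr$V_fw, true_V_ff = fr$V_ff, true_V_fz = fr$V_fz,
          true_V_fp = fr$V_fp, true_rho_p = rho_p_true,
          stringsAsFactors = FALSE
        ))
      }
      warning("non-positive draw in replicate ", rep_id, "; redrawing")
    }
    stop("could not draw a positive measurement record in 100 attempts; ",
         "noise SDs are too large for the true values")
  }

  do.call(rbind, lapply(seq_len(cfg$replicates), one))
}

#' Recovery experiment: bias and RMSE of the measurement reduction
#'
#' Generates `cfg$replicates` noisy records, reduces them with
#' [reduce_measurements()], and compares every recovered quantity (three
#' crimps, three directional fractions, total fraction) with its ground
#' truth.
#'
#' @param cfg A [synthetic_config()]; 50 or more replicates are
#'   recommended for stable summaries.
#' @return A data.frame with one row per quantity: `quantity`, `truth`,
#'   `bias` (mean error), `rmse`, `replicates`.
#' @export
recovery_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  rec <- generate_measurements(cfg)
  red <- suppressWarnings(reduce_measurements(rec, rho_f = cfg$rho_f))
  pairs <- c(C_w = "true_C_w", C_f = "true_C_f", C_z = "true_C_z",
             V_fw = "true_V_fw", V_ff = "true_V_ff", V_fz = "true_V_fz",
             V_fp = "true_V_fp")
  rows <- lapply(names(pairs), function(q) {
    err <- red[[q]] - rec[[pairs[[q]]]]
    data.frame(quantity = q, truth = rec[[pairs[[q]]]][1],
               bias = mean(err), rmse = sqrt(mean(err^2)),
               replicates = nrow(rec), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
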
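# Shared fixtures: small parameter sets and reference-table loaders.

unit_params <- function(...) {
  # unit-diameter, zero-crimp 1x1x1 cell unless overridden
  args <- utils::modifyList(
    list(N = 1, M = 1, T = 1, d_w = 1, d_f = 1, d_z = 1,
         C_w = 0, C_f = 0, C_z = 0),
    list(...)
  )
  do.call(unit_cell_params, args)
}

arch_codes <- c("3DW-P-ZP", "3DW-P-ZO", "3DW-O-ZO")

# deterministic grid of valid parameter sets for property-style loops
param_grid <- function() {
  grid <- expand.grid(N = c(1, 2), M = c(1, 3), T = c(1, 2),
                      d = c(0.3, 0.504), C = c(0, 0.2))
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    unit_cell_params(g$N, g$M, g$T, d_w = g$d, d_f = 0.8 * g$d,
                     d_z = 1.2 * g$d, C_w = g$C, C_f = g$C / 2, C_z = 2 * g$C)
  })
}

ref_fractions <- function() pga_reference("fractions")
ref_mechanics <- function() pga_reference("mechanics")
ref_measurements <- function() pga_reference("measurements")
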
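#' Build a voxelized unit cell of a 3D woven preform
#'
#' Numerical counterpart of [analytical_fractions()]: idealized yarn
#' centerlines are laid out in the unit-cell box of [unit_cell_dims()] and a
#' cross-section is swept along each path and rasterized onto a regular
#' voxel grid. Fractions are then estimated by counting labeled voxels
#' ([voxel_fractions()]).
#'
#' Axes: x runs along the warp (cell length `T d_f + (T+1) d_z`), y along
#' the filling (cell width), z through the thickness
#' (`M d_w + (M+1) d_z`). The yarn inventory matches the analytical model:
#' `N*M` warps, `T*N` fillings (`T*(N+1)` for the orthogonal architecture)
#' and `T*M` z-yarns, on staggered periodic lattices so that straight yarn
#' families do not interpenetrate. The cell is treated as periodic: discs
#' are stamped with minimum-image distances, so yarns pushed across a face
#' wrap around.
#'
#' Paths by architecture:
#' * orthogonal: all three families straight;
#' * semi-interlaced: warp and filling sinusoidal (plain 1/1 interlacing),
#'   z-yarn straight;
#' * plain: all three sinusoidal.
#'
#' Sinusoid amplitude is `(d_self + d_neighbor)/2` and the period twice the
#' crossing-yarn pitch; the arc-length crimp this geometry achieves is
#' reported in the `achieved_crimps` field (compare with the crimp ratios of
#' [unit_cell_params()], which the analytical model uses directly).
#' Overlapping claims are resolved by the fixed priority
#' warp > filling > z-yarn: a later family never overwrites claimed voxels.
#'
#' @inheritParams unit_cell_volume
#' @param resolution Voxels per mm. At least 20 voxels across the smallest
#'   yarn diameter is recommended; less draws a warning.
#' @param cross_section Swept cross-section shape: `"circle"` (validated
#'   default), `"ellipse"` (area-preserving, 1.5 aspect) or `"lenticular"`
#'   (intersection of two yarn-radius circles offset by a quarter
#'   diameter).
#' @param seed Reserved for jitter studies; the builder itself is
#'   deterministic and ignores it.
#' @return An object of class `voxel_unit_cell` with fields `labels` (3D
#'   integer array: 0 void, 1 warp, 2 filling, 3 z-yarn), `dims` (box in
#'   mm), `resolution`, `voxel_size`, `arch`, `params`, `cross_section`,
#'   `achieved_crimps` (fractions) and `ideal_volumes` (continuum
#'   arc-length x area volume per family, mm^3).
#' @examples
#' p <- unit_cell_params(1, 1, 1, 1, 1, 1)
#' cell <- build_unit_cell("3DW-O-ZO", p, resolution = 20)
#' voxel_fractions(cell)
#' @export
build_unit_cell <- function(arch, p, resolution = 40,
                            cross_section = c("circle", "ellipse", "lenticular"),
                            seed = NULL) {
  arch <- as_architecture(arch)
  stopifnot(inherits(p, "unit_cell_params"))
  cross_section <- match.arg(cross_section)
  if (!is.numeric(resolution) || resolution <= 0) {
    stop("resolution must be a positive number of voxels per mm")
  }
  dmin <- min(p$d_w, p$d_f, p$d_z)
  if (dmin * resolution < 20) {
    warning(sprintf(
      "resolution %.3g voxels/mm gives only %.1f voxels across the smallest yarn diameter (>= 20 recommended)",
      resolution, dmin * resolution
    ))
  }

  dims <- unit_cell_dims(arch, p)
  L <- unname(c(dims["length"], dims["width"], dims["thickness"])) # x, y, z
  n <- pmax(2L, as.integer(round(L * resolution)))
  h <- L / n # actual voxel pitch per axis
  centers <- lapply(1:3, function(a) (seq_len(n[a]) - 0.5) * h[a])

  lay <- yarn_layout(arch, p, L)
  labels <- array(0L, dim = n)
  codes <- c(warp = 1L, filling = 2L, z = 3L)
  for (fam in c("warp", "filling", "z")) { # priority order: warp > filling > z
    labels <- stamp_family(labels, lay[[fam]], codes[[fam]], centers, L,
                           cross_section)
  }

  structure(
    list(labels = labels, dims = c(x = L[1], y = L[2], z = L[3]),
         resolution = resolution, voxel_size = h,
         arch = arch$code, params = p, cross_section = cross_section,
         achieved_crimps = vapply(lay, function(f) f$achieved_crimp, 0),
         ideal_volumes = vapply(lay, function(f) f$ideal_volume, 0)),
    class = "voxel_unit_cell"
  )
}

# Yarn lattice + path description per family.
# Each family: axis (1=x, 2=y, 3=z), cross axes, diameter, matrix of
# cross-plane centers, sinusoid amplitude/period/phase (amplitude 0 =
# straight), and which cross axis the sinusoid displaces.
yarn_layout <- function(arch, p, L) {
  N <- p$N; M <- p$M; T <- p$T
  n_fill_rows <- if (arch$code == "3DW-O-ZO") N + 1L else N
  ortho <- arch$code == "3DW-O-ZO"

  fam <- function(axis, cross, d, centers, amp, period, phase) {
    span <- L[axis]
    achieved <- if (amp > 0) sin_arc_crimp(amp, period, span) else 0
    list(axis = axis, cross = cross, d = d, centers = centers,
         amp = amp, period = period, phase = phase,
         achieved_crimp = achieved,
         ideal_volume = nrow(centers) * span * (1 + achieved) * pi * d^2 / 4)
  }

  if (ortho) {
    # Straight families on the packing lattice implied by the unit-cell
    # span factors: yarns alternate with the gap allowances of the other
    # families along each axis, so families sit tangent, not intersecting.
    wy <- seq_len(N) * p$d_f + (seq_len(N) - 0.5) * p$d_w
    wz <- seq_len(M) * p$d_z + (seq_len(M) - 0.5) * p$d_w
    fx <- seq_len(T) * p$d_z + (seq_len(T) - 0.5) * p$d_f
    fz <- (seq_len(n_fill_rows) - 1) * (p$d_w + p$d_z) + p$d_z / 2
    zx <- (seq_len(T) - 1) * (p$d_f + p$d_z) + p$d_z / 2
    zy <- (seq_len(M) - 1) * (p$d_w + p$d_f) + p$d_f / 2
    warp <- expand.grid(j = seq_len(N), i = seq_len(M))
    fill <- expand.grid(k = seq_len(T), i = seq_len(n_fill_rows))
    zy_g <- expand.grid(k = seq_len(T), m = seq_len(M))
    return(list(
      warp = fam(1L, c(2L, 3L), p$d_w,
                 cbind(u = wy[warp$j] %% L[2], v = wz[warp$i] %% L[3]),
                 amp = 0, period = 2 * L[1] / T, phase = rep(0, nrow(warp))),
      filling = fam(2L, c(1L, 3L), p$d_f,
                    cbind(u = fx[fill$k] %% L[1], v = fz[fill$i] %% L[3]),
                    amp = 0, period = 2 * L[2] / N, phase = rep(0, nrow(fill))),
      z = fam(3L, c(1L, 2L), p$d_z,
              cbind(u = zx[zy_g$k] %% L[1], v = zy[zy_g$m] %% L[2]),
              amp = 0, period = 2 * L[3] / M, phase = rep(0, nrow(zy_g)))
    ))
  }

  # Interlaced (plain / semi-interlaced) registry. Warps lie on the packing
  # midplanes and fillings in the gap slots between them; each family
  # shares one sinusoid phase, with the mean line crossing the other
  # family's columns and the extremes diving into the free slots midway
  # between them. At a warp-filling crossing the centre distance is then
  # exactly (d_w + d_f)/2 — tangent — and yarns of one family translate in
  # parallel, so the in-plane families do not interpenetrate; only the
  # z-yarns (plain) lose some volume where their bend tracks the uneven
  # plane spacing.
  wy <- (seq_len(N) - 0.5) * L[2] / N
  wz <- seq_len(M) * p$d_z + (seq_len(M) - 0.5) * p$d_w
  fx <- (seq_len(T) - 0.5) * L[1] / T
  gaps <- (seq_len(M + 1) - 1) * (p$d_w + p$d_z) + p$d_z / 2
  fz <- gaps[((seq_len(n_fill_rows) - 1) %% (M + 1)) + 1]
  # z-yarns drop through the warp sinusoid zero-crossings (slot boundaries
  # along x), midway between warp columns
  zx <- (seq_len(T) - 1) * L[1] / T
  zy <- (((seq_len(M) - 0.5) / M) * L[2] + L[2] / (2 * N)) %% L[2]

  warp <- expand.grid(j = seq_len(N), i = seq_len(M))
  fill <- expand.grid(k = seq_len(T), i = seq_len(n_fill_rows))
  zg <- expand.grid(k = seq_len(T), m = seq_len(M))

  plain <- arch$code == "3DW-P-ZP"
  half <- pi / 2
  list(
    warp = fam(1L, c(2L, 3L), p$d_w,
               cbind(u = wy[warp$j], v = wz[warp$i] %% L[3]),
               amp = (p$d_w + p$d_f) / 2, period = 2 * L[1] / T,
               phase = rep(half, nrow(warp))),
    filling = fam(2L, c(1L, 3L), p$d_f,
                  cbind(u = fx[fill$k], v = fz[fill$i] %% L[3]),
                  amp = (p$d_f + p$d_w) / 2, period = 2 * L[2] / N,
                  phase = rep(half, nrow(fill))),
    z = fam(3L, c(1L, 2L), p$d_z,
            cbind(u = zx[zg$k], v = zy[zg$m]),
            amp = if (plain) (p$d_z + p$d_w) / 2 else 0,
            period = 2 * L[3] / M,
            phase = rep(-(pi * M / L[3]) * wz[1], nrow(zg)))
  )
}

# arc-length crimp of u -> A sin(2 pi u / lambda) over span S
sin_arc_crimp <- function(A, lambda, S) {
  k <- 2 * pi / lambda
  f <- function(u) sqrt(1 + (A * k * cos(k * u))^2)
  stats::integrate(f, 0, S, subdivisions = 400L)$value / S - 1
}

stamp_family <- function(labels, fam, code, centers, L, cross_section) {
  axis <- fam$axis
  cr <- fam$cross
  along <- centers[[axis]]
  u_grid <- centers[[cr[1]]]
  v_grid <- centers[[cr[2]]]
  Lu <- L[cr[1]]; Lv <- L[cr[2]]
  r <- fam$d / 2

  # periodic squared distances from every cross-plane grid line to a center
  pdist <- function(g, c0, Lg) {
    d <- abs(g - c0 %% Lg)
    pmin(d, Lg - d)
  }

  n_along <- length(along)
  for (is in seq_len(n_along)) {
    u0 <- along[is]
    # slice of the label array perpendicular to the yarn axis
    slice <- switch(axis,
                    `1` = labels[is, , ],
                    `2` = labels[, is, ],
                    `3` = labels[, , is])
    free <- slice == 0L
    if (!any(free)) next
    hit <- matrix(FALSE, nrow(slice), ncol(slice))
    omega <- 2 * pi / fam$period
    for (yy in seq_len(nrow(fam$centers))) {
      cu <- fam$centers[yy, 1]
      cv <- fam$centers[yy, 2]
      stretch <- 1
      if (fam$amp > 0) {
        # sinusoidal offset displaces the second cross axis (the one the
        # yarn bends through: z for in-plane yarns, y for z-yarns); the
        # slice of the tilted tube is an ellipse elongated along the
        # offset direction by the local slope factor, which keeps the
        # rasterized volume at arc length x cross-section area
        ph <- omega * u0 + fam$phase[yy]
        cv <- cv + fam$amp * sin(ph)
        stretch <- sqrt(1 + (fam$amp * omega * cos(ph))^2)
      }
      du <- pdist(u_grid, cu, Lu)
      dv <- pdist(v_grid, cv, Lv) / stretch
      hit <- hit | cross_section_mask(du, dv, r, cross_section)
    }
    slice[free & hit] <- code
    switch(axis,
           `1` = labels[is, , ] <- slice,
           `2` = labels[, is, ] <- slice,
           `3` = labels[, , is] <- slice)
  }
  labels
}

# du, dv: nonnegative periodic distances along the two cross axes
cross_section_mask <- function(du, dv, r, shape) {
  switch(shape,
    circle = outer(du^2, dv^2, `+`) <= r^2,
    ellipse = {
      a <- r * sqrt(1.5); b <- r / sqrt(1.5)
      outer((du / a)^2, (dv / b)^2, `+`) <= 1
    },
    lenticular = {
      off <- r / 2
      outer(du^2, (dv + off)^2, `+`) <= r^2
    }
  )
}

#' @export
print.voxel_unit_cell <- function(x, ...) {
  cat(sprintf(
    "<voxel_unit_cell> %s  %d x %d x %d voxels (%.3g/mm), box %.2f x %.2f x %.2f mm, %s cross-section\n",
    x$arch, dim(x$labels)[1], dim(x$labels)[2], dim(x$labels)[3],
    x$resolution, x$dims[1], x$dims[2], x$dims[3], x$cross_section
  ))
  invisible(x)
}

#' Fiber-volume and porosity fractions of a voxel unit cell
#'
#' Counts labeled voxels per category. By construction the four fractions
#' (warp, filling, z, void) partition the grid and sum to exactly 100%.
#'
#' @param cell A [build_unit_cell()] result.
#' @return A [fraction_set()] with `source = "voxel"`.
#' @export
voxel_fractions <- function(cell) {
  stopifnot(inherits(cell, "voxel_unit_cell"))
  total <- length(cell$labels)
  counts <- tabulate(cell$labels + 1L, nbins = 4L) # void, warp, filling, z
  fraction_set(100 * counts[2] / total,
               100 * counts[3] / total,
               100 * counts[4] / total,
               source = "voxel", arch = cell$arch)
}

#' Export a voxel unit cell
#'
#' `write_voxel_cell()` writes the label grid as a flat binary file
#' (`<prefix>.raw`, one byte per voxel, x fastest) plus a JSON header
#' (`<prefix>.json`) recording grid shape, voxel size, box dimensions and
#' label codes. `write_voxel_vtk()` writes an ASCII VTK structured-points
#' file for visualization.
#'
#' @param cell A [build_unit_cell()] result.
#' @param prefix Output path prefix (without extension).
#' @return The paths written, invisibly.
#' @export
write_voxel_cell <- function(cell, prefix) {
  stopifnot(inherits(cell, "voxel_unit_cell"))
  raw_path <- paste0(prefix, ".raw")
  json_path <- paste0(prefix, ".json")
  writeBin(as.raw(cell$labels), raw_path)
  header <- list(
    shape = dim(cell$labels), order = "x-fastest",
    voxel_size_mm = cell$voxel_size, box_mm = as.list(cell$dims),
    arch = cell$arch, cross_section = cell$cross_section,
    labels = list(void = 0, warp = 1, filling = 2, z = 3)
  )
  jsonlite::write_json(header, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(raw = raw_path, json = json_path))
}

#' @rdname write_voxel_cell
#' @param path Output path for the VTK file.
#' @export
write_voxel_vtk <- function(cell, path) {
  stopifnot(inherits(cell, "voxel_unit_cell"))
  n <- dim(cell$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "wovencell voxel unit cell",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
    "ORIGIN 0 0 0",
    sprintf("SPACING %g %g %g",
            cell$voxel_size[1], cell$voxel_size[2], cell$voxel_size[3]),
    sprintf("POINT_DATA %d", prod(n)),
    "SCALARS yarn_label int 1",
    "LOOKUP_TABLE default"
  ), con)
  writeLines(paste(as.integer(cell$labels), collapse = " "), con)
  invisible(path)
}
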
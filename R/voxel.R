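#' Voxelize a clipped plot cloud
#'
#' Divides the plot box into a regular grid of voxels (default
#' 0.5 x 0.5 x 0.25 m) and counts the points falling in each half-open
#' voxel box. A voxel is flagged *vegetated* when it holds at least
#' `occupancy_threshold` points (default 5) - a rule that also filters
#' the "ghost point" noise of phase-shift scanners. With the default
#' 27 m plot box and 0.5-15.5 m height window the grid is
#' 54 x 54 x 60 = 174,960 voxels.
#'
#' The grid origin is anchored at the plot box's lower corner
#' (`center - side/2`, `z_min`), so identical inputs always produce
#' identical grids.
#'
#' @param cloud A [point_cloud()] already clipped by [clip_to_plot()].
#' @param geom The [plot_geometry()] used for clipping.
#' @param dx,dy,dz Voxel edge lengths in metres.
#' @param occupancy_threshold Minimum point count for a vegetated voxel.
#' @return An object of class `voxel_grid`: counts and vegetated flags as
#'   `nx x ny x nz` arrays plus grid geometry.
#' @export
voxelize <- function(cloud, geom, dx = 0.5, dy = 0.5, dz = 0.25,
                     occupancy_threshold = 5L) {
  stopifnot(inherits(geom, "plot_geometry"))
  side <- geom$square_side
  zspan <- geom$z_max - geom$z_min
  nd <- c(side / dx, side / dy, zspan / dz)
  if (any(abs(nd - round(nd)) > 1e-8))
    stop(sprintf(
      "voxel sizes (%g, %g, %g) must evenly divide the plot box (%g x %g x %g m)",
      dx, dy, dz, side, side, zspan), call. = FALSE)
  nx <- as.integer(round(nd[1])); ny <- as.integer(round(nd[2]))
  nz <- as.integer(round(nd[3]))
  ox <- geom$center_x - side / 2
  oy <- geom$center_y - side / 2
  oz <- geom$z_min

  counts <- array(0L, dim = c(nx, ny, nz))
  if (nrow(cloud) > 0) {
    i <- as.integer(floor((cloud$x - ox) / dx))
    j <- as.integer(floor((cloud$y - oy) / dy))
    k <- as.integer(floor((cloud$z - oz) / dz))
    if (any(i < 0L | i >= nx | j < 0L | j >= ny | k < 0L | k >= nz))
      stop("cloud contains points outside the plot box; clip_to_plot() first",
           call. = FALSE)
    lin <- 1L + i + nx * (j + ny * k)
    counts[] <- tabulate(lin, nbins = nx * ny * nz)
  }
  structure(list(
    origin_x = ox, origin_y = oy, origin_z = oz,
    dx = dx, dy = dy, dz = dz, nx = nx, ny = ny, nz = nz,
    occupancy_threshold = as.integer(occupancy_threshold),
    counts = counts,
    vegetated = counts >= occupancy_threshold
  ), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels of %g x %g x %g m (%d total)\n",
    x$nx, x$ny, x$nz, x$dx, x$dy, x$dz, x$nx * x$ny * x$nz))
  cat(sprintf("  %d points, %d vegetated voxels (threshold %d)\n",
              sum(x$counts), sum(x$vegetated), x$occupancy_threshold))
  invisible(x)
}

#' Default understory strata
#'
#' The five height classes used for stratified density profiles:
#' forest floor (FF, 0.5-1 m), shrubs (Sh, 1-2 m), lower understory
#' (LU, 2-5 m), upper understory (UU, 5-10 m) and subcanopy
#' (Sc, 10 m up to the top of the analysed box, 15.5 m by default).
#'
#' @param z_max Upper bound of the subcanopy stratum (m).
#' @return Data frame with columns `stratum`, `z_low`, `z_high`.
#' @export
default_strata <- function(z_max = 15.5) {
  data.frame(stratum = c("FF", "Sh", "LU", "UU", "Sc"),
             z_low = c(0.5, 1, 2, 5, 10),
             z_high = c(1, 2, 5, 10, z_max),
             stringsAsFactors = FALSE)
}

stratum_layers <- function(grid, z_low, z_high) {
  k0 <- (z_low - grid$origin_z) / grid$dz
  k1 <- (z_high - grid$origin_z) / grid$dz
  if (abs(k0 - round(k0)) > 1e-8 || abs(k1 - round(k1)) > 1e-8)
    stop(sprintf(
      "stratum [%g, %g) is not aligned to %g m voxel layers", z_low, z_high,
      grid$dz), call. = FALSE)
  seq.int(round(k0) + 1L, round(k1))
}

#' Plant Density Index by stratum
#'
#' PDI of a stratum is the fraction of vegetated voxels among all voxels
#' whose base lies in `[z_low, z_high)` - a density in `[0, 1]`. Strata
#' must be contiguous multiples of the voxel height.
#'
#' @param grid A [voxelize()] result.
#' @param strata Data frame with columns `stratum`, `z_low`, `z_high`;
#'   defaults to [default_strata()] capped at the grid top.
#' @param plot_id Identifier copied into the output.
#' @return Data frame: `plot_id`, `stratum`, `z_low`, `z_high`,
#'   `n_voxels`, `n_vegetated`, `pdi`.
#' @export
pdi_by_stratum <- function(grid, strata = NULL, plot_id = NA_character_) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(strata))
    strata <- default_strata(z_max = grid$origin_z + grid$nz * grid$dz)
  per_layer <- apply(grid$vegetated, 3, sum)
  res <- lapply(seq_len(nrow(strata)), function(s) {
    ks <- stratum_layers(grid, strata$z_low[s], strata$z_high[s])
    nv <- grid$nx * grid$ny * length(ks)
    ng <- sum(per_layer[ks])
    data.frame(plot_id = plot_id, stratum = strata$stratum[s],
               z_low = strata$z_low[s], z_high = strata$z_high[s],
               n_voxels = nv, n_vegetated = ng, pdi = ng / nv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Vertical PDI slice profile
#'
#' The detailed vertical density profile: one PDI value per contiguous
#' horizontal slice (default 0.5 m, aggregating two 0.25 m voxel
#' layers), spanning the full height window of the grid.
#'
#' @param grid A [voxelize()] result.
#' @param slice_height Slice thickness (m); must be a multiple of the
#'   voxel height `dz` and tile the grid height evenly.
#' @param plot_id Identifier copied into the output.
#' @return Data frame: `plot_id`, `z_low`, `z_mid`, `pdi`.
#' @export
slice_profile <- function(grid, slice_height = 0.5, plot_id = NA_character_) {
  stopifnot(inherits(grid, "voxel_grid"))
  m <- slice_height / grid$dz
  if (abs(m - round(m)) > 1e-8)
    stop(sprintf("slice_height (%g) must be a multiple of dz (%g)",
                 slice_height, grid$dz), call. = FALSE)
  m <- as.integer(round(m))
  if (grid$nz %% m != 0L)
    stop(sprintf("slice_height (%g) must evenly tile the grid height (%g m)",
                 slice_height, grid$nz * grid$dz), call. = FALSE)
  nsl <- grid$nz %/% m
  per_layer <- apply(grid$vegetated, 3, sum)
  sl <- rep(seq_len(nsl), each = m)
  veg <- tapply(per_layer, sl, sum)
  denom <- grid$nx * grid$ny * m
  data.frame(plot_id = plot_id,
             z_low = grid$origin_z + (seq_len(nsl) - 1L) * slice_height,
             z_mid = grid$origin_z + (seq_len(nsl) - 0.5) * slice_height,
             pdi = as.numeric(veg) / denom,
             stringsAsFactors = FALSE)
}

#' Full stratified density profile for one plot
#'
#' Convenience wrapper bundling [pdi_by_stratum()] and [slice_profile()]
#' for a single plot cloud.
#'
#' @inheritParams voxelize
#' @param plot_id Plot identifier.
#' @param strata See [pdi_by_stratum()].
#' @param slice_height See [slice_profile()].
#' @return An object of class `strata_profile`: list with `plot_id`,
#'   `strata` (per-stratum PDI) and `slices` (slice profile).
#' @export
strata_profile <- function(cloud, geom, plot_id = NA_character_,
                           dx = 0.5, dy = 0.5, dz = 0.25,
                           occupancy_threshold = 5L, strata = NULL,
                           slice_height = 0.5) {
  grid <- voxelize(cloud, geom, dx, dy, dz, occupancy_threshold)
  structure(list(
    plot_id = plot_id,
    strata = pdi_by_stratum(grid, strata, plot_id = plot_id),
    slices = slice_profile(grid, slice_height, plot_id = plot_id)
  ), class = "strata_profile")
}

#' @export
print.strata_profile <- function(x, ...) {
  cat(sprintf("<strata_profile> plot %s\n", x$plot_id))
  print(x$strata[, c("stratum", "z_low", "z_high", "pdi")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.strata_profile <- function(x, ...) {
  graphics::plot(x$slices$pdi, x$slices$z_mid, type = "b", pch = 16,
                 col = "grey50", xlab = "PDI", ylab = "height (m)",
                 xlim = c(0, max(0.05, max(x$slices$pdi, x$strata$pdi))),
                 main = paste("PDI profile", x$plot_id), ...)
  with(x$strata, graphics::segments(pdi, z_low, pdi, z_high, lwd = 2))
  invisible(x)
}
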
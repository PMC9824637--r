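#' Construct a point cloud
#'
#' The common currency of all lidar stages: a data frame of point
#' coordinates in metres with optional return numbers and LAS
#' classification codes. After height normalization, `z` is interpreted
#' as height above ground.
#'
#' @param x,y,z Numeric coordinate vectors of equal length (metres).
#' @param return_number Positive integer vector (recycled); the echo
#'   index of each point. Defaults to 1 (first returns).
#' @param classification Integer LAS classification codes (recycled);
#'   2 denotes ground per the LAS convention. Defaults to 1.
#' @return An object of class `point_cloud`: a data frame with columns
#'   `x`, `y`, `z`, `return_number`, `classification`.
#' @examples
#' pc <- point_cloud(runif(10), runif(10), runif(10, 0, 5))
#' n_points(pc)
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(),
                        return_number = 1L, classification = 1L) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y and z must have identical length", call. = FALSE)
  if (n > 0) {
    return_number <- rep_len(as.integer(return_number), n)
    classification <- rep_len(as.integer(classification), n)
    if (any(return_number < 1L))
      stop("return_number must be a positive integer", call. = FALSE)
  } else {
    return_number <- integer()
    classification <- integer()
  }
  structure(
    data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
               return_number = return_number,
               classification = classification),
    class = c("point_cloud", "data.frame")
  )
}

#' Number of points in a point cloud
#' @param cloud A [point_cloud()].
#' @return Integer count.
#' @export
n_points <- function(cloud) nrow(cloud)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points\n", nrow(x)))
  if (nrow(x) > 0) {
    rng <- function(v) sprintf("[%.3f, %.3f]", min(v), max(v))
    cat(sprintf("  x %s  y %s  z %s\n", rng(x$x), rng(x$y), rng(x$z)))
    cat(sprintf("  first returns: %d  ground-classified: %d\n",
                sum(x$return_number == 1L), sum(x$classification == 2L)))
  }
  invisible(x)
}

as_point_cloud <- function(df) {
  point_cloud(df$x, df$y, df$z,
              if (is.null(df$return_number)) 1L else df$return_number,
              if (is.null(df$classification)) 1L else df$classification)
}

#' Plot geometry: the analysed box around a field plot
#'
#' Field plots are circular (15 m radius) but the analysed TLS space is a
#' parallelepiped: a square base centred on the plot centre and a height
#' window above ground. Defaults follow the standard protocol: 27 m side,
#' heights 0.5-15.5 m (the lower bound avoids ground vegetation and
#' terrain residue, the upper one the working range of hand-held
#' scanners). The circular radius is retained only for linking field
#' (tree-list) data.
#'
#' @param center_x,center_y Plot centre (metres).
#' @param square_side Side of the square base (m), default 27.
#' @param z_min,z_max Height window above ground (m), default 0.5 and 15.5.
#' @param plot_radius Field plot radius (m), default 15.
#' @return An object of class `plot_geometry`.
#' @export
plot_geometry <- function(center_x = 0, center_y = 0, square_side = 27,
                          z_min = 0.5, z_max = 15.5, plot_radius = 15) {
  if (square_side <= 0) stop("square_side must be > 0", call. = FALSE)
  if (!(z_max > z_min && z_min >= 0))
    stop("need z_max > z_min >= 0", call. = FALSE)
  structure(list(center_x = center_x, center_y = center_y,
                 square_side = square_side, z_min = z_min, z_max = z_max,
                 plot_radius = plot_radius),
            class = "plot_geometry")
}

#' @export
print.plot_geometry <- function(x, ...) {
  cat(sprintf(
    "<plot_geometry> centre (%.2f, %.2f), %g m square, heights [%g, %g) m\n",
    x$center_x, x$center_y, x$square_side, x$z_min, x$z_max))
  invisible(x)
}

#' Clip a normalized cloud to a plot box
#'
#' Retains points inside the half-open box
#' `[cx - s/2, cx + s/2) x [cy - s/2, cy + s/2) x [z_min, z_max)`.
#' Lower bounds are closed and upper bounds open so that adjacent boxes,
#' voxels and strata never double-count a point. Idempotent.
#'
#' @param cloud A height-normalized [point_cloud()].
#' @param geom A [plot_geometry()].
#' @return The clipped `point_cloud` (possibly empty).
#' @export
clip_to_plot <- function(cloud, geom) {
  stopifnot(inherits(geom, "plot_geometry"))
  h <- geom$square_side / 2
  keep <- cloud$x >= geom$center_x - h & cloud$x < geom$center_x + h &
    cloud$y >= geom$center_y - h & cloud$y < geom$center_y + h &
    cloud$z >= geom$z_min & cloud$z < geom$z_max
  as_point_cloud(cloud[keep, , drop = FALSE])
}

#' Height-normalize a point cloud with a grid ground model
#'
#' Estimates a ground surface on a regular horizontal grid and subtracts
#' it, so that `z` becomes height above ground. Per cell, the ground
#' elevation is the mean of ground-classified points (class 2) when the
#' cloud carries a ground classification, otherwise the lowest point in
#' the cell (a conservative estimate for unclassified clouds). Cells
#' without a ground estimate are filled from their neighbours, and the
#' cell-centre grid is interpolated bilinearly at each point.
#'
#' Suitable for the gentle terrain this workflow assumes; clouds that are
#' already normalized pass through essentially unchanged (ground stays at
#' zero).
#'
#' @param cloud A [point_cloud()] with absolute elevations.
#' @param ground_resolution Ground grid cell size in metres (default 1).
#' @return A `point_cloud` with the same points; only `z` changes.
#' @export
normalize_heights <- function(cloud, ground_resolution = 1) {
  if (nrow(cloud) < 3)
    stop("need at least 3 points to estimate a ground surface", call. = FALSE)
  res <- ground_resolution
  x0 <- floor(min(cloud$x) / res) * res
  y0 <- floor(min(cloud$y) / res) * res
  nx <- max(1L, ceiling((max(cloud$x) - x0) / res + 1e-9))
  ny <- max(1L, ceiling((max(cloud$y) - y0) / res + 1e-9))
  ci <- pmin(nx - 1L, pmax(0L, as.integer(floor((cloud$x - x0) / res))))
  cj <- pmin(ny - 1L, pmax(0L, as.integer(floor((cloud$y - y0) / res))))
  lin <- ci + nx * cj + 1L

  has_ground_class <- any(cloud$classification == 2L)
  gz <- rep(NA_real_, nx * ny)
  if (has_ground_class) {
    sel <- cloud$classification == 2L
    agg <- tapply(cloud$z[sel], lin[sel], mean)
  } else {
    agg <- tapply(cloud$z, lin, min)
  }
  gz[as.integer(names(agg))] <- as.numeric(agg)
  gmat <- matrix(gz, nrow = ny, ncol = nx, byrow = TRUE)
  gmat <- fill_na_grid(gmat)

  # bilinear interpolation over cell centres, clamped at the margins
  cx <- x0 + (seq_len(nx) - 0.5) * res
  cy <- y0 + (seq_len(ny) - 0.5) * res
  if (nx == 1 || ny == 1) {
    ground <- gmat[cbind(cj + 1L, ci + 1L)]
  } else {
    xp <- pmin(max(cx), pmax(min(cx), cloud$x))
    yp <- pmin(max(cy), pmax(min(cy), cloud$y))
    ground <- pracma::interp2(cx, cy, gmat, xp, yp)
  }
  out <- cloud
  out$z <- cloud$z - ground
  as_point_cloud(out)
}

# iteratively fill NA cells from the mean of available 8-neighbours
fill_na_grid <- function(m) {
  if (!anyNA(m)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(nr + nc)) {
    nas <- which(is.na(m), arr.ind = TRUE)
    if (nrow(nas) == 0L) break
    vals <- numeric(nrow(nas)); ok <- logical(nrow(nas))
    for (k in seq_len(nrow(nas))) {
      i <- nas[k, 1]; j <- nas[k, 2]
      nb <- m[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      nb <- nb[!is.na(nb)]
      if (length(nb) > 0) { vals[k] <- mean(nb); ok[k] <- TRUE }
    }
    m[nas[ok, , drop = FALSE]] <- vals[ok]
    if (all(ok)) break
  }
  m
}
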
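# Synthetic forest scenes with known ground truth.
#
# Scenes live in height-above-ground coordinates on a fixed 0.5 x 0.5 x
# 0.25 m voxel lattice: the set of *occupied* voxels (foliage clumps,
# crown volumes, stem columns) IS the scene's vegetation, so the truth
# (per-stratum occupancy fractions) is exact by construction and
# independent of any sampled point cloud. Terrain enters only when a
# cloud is sampled (a planar slope is added to z).

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specify a synthetic forest scene
#'
#' Parameters of a generated stand. `understory_intensity_LU` and
#' `understory_intensity_UU` are the target expected fractions of
#' occupied voxels in the lower (2-5 m) and upper (5-10 m) understory
#' strata. `beech_like` stands are dense-canopied (low ALS
#' transmission), `pine_like` stands open (high transmission).
#'
#' @param extent_x,extent_y Scene extent (m); default 27 (one plot box).
#' @param stand_type `"beech_like"` or `"pine_like"`.
#' @param stem_density Overstory stems per hectare.
#' @param canopy_base,canopy_top Crown layer bounds (m).
#' @param understory_intensity_LU,understory_intensity_UU Target voxel
#'   occupancy fractions in `[0, 1]`.
#' @param ground_slope Terrain slope (fraction, rise along x).
#' @param seed Integer seed fixing all randomness of the scene.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(extent_x = 27, extent_y = 27,
                       stand_type = c("beech_like", "pine_like"),
                       stem_density = 400, canopy_base = 12,
                       canopy_top = 22, understory_intensity_LU = 0.2,
                       understory_intensity_UU = 0.15, ground_slope = 0,
                       seed = 1L) {
  stand_type <- match.arg(stand_type)
  ints <- c(understory_intensity_LU, understory_intensity_UU)
  if (any(ints < 0 | ints > 1))
    stop("understory intensities must lie in [0, 1] (feasible range)",
         call. = FALSE)
  if (!(canopy_top > canopy_base && canopy_base > 0))
    stop("need canopy_top > canopy_base > 0", call. = FALSE)
  structure(list(extent_x = extent_x, extent_y = extent_y,
                 stand_type = stand_type, stem_density = stem_density,
                 canopy_base = canopy_base, canopy_top = canopy_top,
                 understory_intensity_LU = understory_intensity_LU,
                 understory_intensity_UU = understory_intensity_UU,
                 ground_slope = ground_slope, seed = as.integer(seed)),
            class = "scene_spec")
}

# clumped Bernoulli voxel field over a horizontal band.
# Hierarchical thinning: 2x2x2-voxel blocks are active with probability
# sqrt(fill) and voxels inside active blocks occupied with probability
# sqrt(fill), so the marginal occupancy is exactly `fill` while clumps
# emerge at the ~1 m scale. `fill` may be a per-column vector (length
# nx*ny, column-major in i then j) and `k_hi` a per-column upper layer
# bound for bands of varying thickness.
clumped_voxels <- function(nx, ny, k_lo, k_hi, fill) {
  k_max <- max(k_hi)
  nk <- k_max - k_lo + 1L
  if (nk <= 0L) return(cbind(i = integer(), j = integer(), k = integer()))
  ncol_xy <- nx * ny
  fill_col <- rep_len(fill, ncol_xy)
  k_hi_col <- rep_len(k_hi, ncol_xy)
  q <- sqrt(fill_col)
  # block index per voxel (blocks of 2 cells in each dimension)
  bx <- ceiling(nx / 2); by <- ceiling(ny / 2); bz <- ceiling(nk / 2)
  block_active <- array(stats::runif(bx * by * bz), dim = c(bx, by, bz))
  ii <- rep(seq_len(nx), times = ny)
  jj <- rep(seq_len(ny), each = nx)
  bi <- (ii + 1L) %/% 2L; bj <- (jj + 1L) %/% 2L
  out <- vector("list", nk)
  for (kk in seq_len(nk)) {
    k <- k_lo + kk - 1L
    bk <- (kk + 1L) %/% 2L
    p_block <- block_active[cbind(bi, bj, bk)] < q
    occ <- p_block & (stats::runif(ncol_xy) < q) & (k <= k_hi_col)
    idx <- which(occ)
    out[[kk]] <- cbind(i = ii[idx], j = jj[idx], k = rep(k, length(idx)))
  }
  do.call(rbind, out)
}

stratum_of_z <- function(z) {
  cut(z, breaks = c(-Inf, 0.5, 1, 2, 5, 10, Inf),
      labels = c("below", "FF", "Sh", "LU", "UU", "Sc"), right = FALSE)
}

voxel_df <- function(ijk, kind) {
  if (is.null(ijk) || nrow(ijk) == 0)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      kind = character(), stringsAsFactors = FALSE))
  data.frame(x = (ijk[, "i"] - 0.5) * 0.5,
             y = (ijk[, "j"] - 0.5) * 0.5,
             z = (ijk[, "k"] - 0.5) * 0.25,
             kind = kind, stringsAsFactors = FALSE)
}

#' Generate a synthetic forest scene
#'
#' Realizes a [scene_spec()]: overstory stems from a homogeneous Poisson
#' process with lognormal DBH, ellipsoidal crowns between `canopy_base`
#' and `canopy_top`, trunk columns below the crowns, and clumped
#' understory foliage whose expected voxel occupancy per stratum equals
#' the requested intensities. A field tree list accompanies the scene:
#' counts of small (DBH < 9 cm) and intermediate (9-20 cm) trees are
#' Poisson-coupled to the LU and UU intensities, so rank correlations
#' between field counts and density profiles carry signal.
#'
#' All randomness flows from `spec$seed`; the same spec yields the same
#' scene.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `forest_scene`: `spec`, `stems` (overstory),
#'   `field_trees` (all DBH records), `occupied` (occupied voxel centres
#'   with `kind` foliage/crown/stem), `transmission` (default per-crown
#'   ALS transmission for the stand type).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    ex <- spec$extent_x; ey <- spec$extent_y
    nx <- as.integer(round(ex / 0.5)); ny <- as.integer(round(ey / 0.5))
    area_ha <- ex * ey / 1e4

    n_stems <- stats::rpois(1, spec$stem_density * area_ha)
    meanlog <- if (spec$stand_type == "beech_like") log(35) else log(30)
    sdlog <- if (spec$stand_type == "beech_like") 0.30 else 0.25
    stems <- data.frame(
      x = stats::runif(n_stems, 0, ex), y = stats::runif(n_stems, 0, ey),
      dbh_cm = stats::rlnorm(n_stems, meanlog, sdlog),
      crown_top = spec$canopy_top - stats::runif(n_stems, 0, 2),
      crown_base = pmax(1, spec$canopy_base + stats::runif(n_stems, -1, 1)),
      crown_radius = stats::runif(n_stems, 1.5, 3)
    )

    occ <- list()
    # crown voxels (ellipsoid per stem, bounding-box scan)
    if (n_stems > 0) {
      crowns <- lapply(seq_len(n_stems), function(s) {
        st <- stems[s, ]
        zc <- (st$crown_base + st$crown_top) / 2
        rz <- (st$crown_top - st$crown_base) / 2
        i_rng <- max(1L, base::floor((st$x - st$crown_radius) / 0.5) + 1L):
          min(nx, ceiling((st$x + st$crown_radius) / 0.5))
        j_rng <- max(1L, base::floor((st$y - st$crown_radius) / 0.5) + 1L):
          min(ny, ceiling((st$y + st$crown_radius) / 0.5))
        k_rng <- max(1L, base::floor(st$crown_base / 0.25) + 1L):
          ceiling(st$crown_top / 0.25)
        g <- expand.grid(i = i_rng, j = j_rng, k = k_rng)
        cx <- (g$i - 0.5) * 0.5; cy <- (g$j - 0.5) * 0.5
        cz <- (g$k - 0.5) * 0.25
        inside <- ((cx - st$x)^2 + (cy - st$y)^2) / st$crown_radius^2 +
          ((cz - zc)^2) / rz^2 <= 1
        as.matrix(g[inside, , drop = FALSE])
      })
      cr <- unique(do.call(rbind, crowns))
      if (!is.null(cr) && nrow(cr) > 0)
        occ$crown <- voxel_df(cr, "crown")
      # trunk columns: one voxel column from 0 up to the crown base
      tr <- lapply(seq_len(n_stems), function(s) {
        st <- stems[s, ]
        i <- min(nx, base::floor(st$x / 0.5) + 1L)
        j <- min(ny, base::floor(st$y / 0.5) + 1L)
        k <- seq_len(base::floor(st$crown_base / 0.25))
        cbind(i = rep(i, length(k)), j = rep(j, length(k)), k = k)
      })
      occ$stem <- voxel_df(unique(do.call(rbind, tr)), "stem")
    }
    # clumped understory foliage per stratum band
    if (spec$understory_intensity_LU > 0)
      occ$lu <- voxel_df(clumped_voxels(nx, ny, k_lo = 9L, k_hi = 20L,
                                        fill = spec$understory_intensity_LU),
                         "foliage")
    if (spec$understory_intensity_UU > 0)
      occ$uu <- voxel_df(clumped_voxels(nx, ny, k_lo = 21L, k_hi = 40L,
                                        fill = spec$understory_intensity_UU),
                         "foliage")
    occupied <- do.call(rbind, occ)
    if (is.null(occupied)) occupied <- voxel_df(NULL, character())
    rownames(occupied) <- NULL

    # field tree list: overstory plus understory trees coupled to density
    n_small <- stats::rpois(1, (60 * spec$understory_intensity_LU + 2) *
                              area_ha / 0.0729)
    n_mid <- stats::rpois(1, (40 * spec$understory_intensity_UU + 2) *
                            area_ha / 0.0729)
    field_trees <- data.frame(
      x = stats::runif(n_small + n_mid, 0, ex),
      y = stats::runif(n_small + n_mid, 0, ey),
      dbh_cm = c(stats::runif(n_small, 2, 9), stats::runif(n_mid, 9, 20))
    )
    field_trees <- rbind(field_trees,
                         stems[, c("x", "y", "dbh_cm"), drop = FALSE])

    structure(list(
      spec = spec, stems = stems, field_trees = field_trees,
      occupied = occupied,
      transmission = if (spec$stand_type == "beech_like") 0.3 else 0.6
    ), class = "forest_scene")
  })
}

#' @export
print.forest_scene <- function(x, ...) {
  cat(sprintf(
    "<forest_scene> %s, %g x %g m, %d stems, %d occupied voxels\n",
    x$spec$stand_type, x$spec$extent_x, x$spec$extent_y, nrow(x$stems),
    nrow(x$occupied)))
  invisible(x)
}

#' True stratified voxel occupancy of a scene region
#'
#' Computes per-stratum occupied-voxel fractions directly from the scene
#' geometry (independent of any sampled point cloud) for a rectangular
#' region, using the same denominators as the TLS pipeline.
#'
#' @param scene A [generate_scene()] result.
#' @param xmin,xmax,ymin,ymax Region bounds (m); default the full scene.
#' @param strata See [pdi_by_stratum()]; defaults to [default_strata()].
#' @return Data frame: `stratum`, `z_low`, `z_high`, `true_pdi`.
#' @export
scene_truth_pdi <- function(scene, xmin = 0, xmax = scene$spec$extent_x,
                            ymin = 0, ymax = scene$spec$extent_y,
                            strata = default_strata()) {
  occ <- scene$occupied
  inb <- occ$x >= xmin & occ$x < xmax & occ$y >= ymin & occ$y < ymax
  occ <- occ[inb, , drop = FALSE]
  n_cols <- round((xmax - xmin) / 0.5) * round((ymax - ymin) / 0.5)
  res <- lapply(seq_len(nrow(strata)), function(s) {
    zl <- strata$z_low[s]; zh <- strata$z_high[s]
    nv <- n_cols * round((zh - zl) / 0.25)
    ng <- sum(occ$z >= zl & occ$z < zh)
    data.frame(stratum = strata$stratum[s], z_low = zl, z_high = zh,
               true_pdi = ng / nv, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Sample a TLS-like point cloud from a scene
#'
#' Emulates a ground-based (hand-held) scan of the plot box: every
#' occupied voxel below 16 m receives a Poisson number of surface points
#' (uniform within the voxel plus Gaussian coordinate noise), thinned
#' with height as the view from below degrades; ground points are added
#' on a dense grid. At the default density every truly occupied voxel
#' receives at least the five points required by the occupancy rule with
#' overwhelming probability.
#'
#' @param scene A [generate_scene()] result.
#' @param geom A [plot_geometry()] inside the scene extent.
#' @param pulse_density Point density scale (points per cubic metre at
#'   ground level), default 800.
#' @param noise_sd Gaussian coordinate noise (m), default 0.005.
#' @param seed Seed for the sampling draw.
#' @return A [point_cloud()] in absolute coordinates (terrain slope
#'   included), classification 2 for ground points.
#' @export
sample_tls <- function(scene, geom, pulse_density = 800, noise_sd = 0.005,
                       seed = 1L) {
  stopifnot(inherits(scene, "forest_scene"), inherits(geom, "plot_geometry"))
  with_seed(seed, {
    h <- geom$square_side / 2 + 1  # small margin so clipping is exercised
    occ <- scene$occupied
    inb <- occ$x >= geom$center_x - h & occ$x < geom$center_x + h &
      occ$y >= geom$center_y - h & occ$y < geom$center_y + h & occ$z < 16
    occ <- occ[inb, , drop = FALSE]
    lam <- pulse_density * 0.5 * 0.5 * 0.25 / (1 + occ$z / 20)
    npts <- stats::rpois(nrow(occ), lam)
    idx <- rep.int(seq_len(nrow(occ)), npts)
    x <- occ$x[idx] + stats::runif(length(idx), -0.25, 0.25)
    y <- occ$y[idx] + stats::runif(length(idx), -0.25, 0.25)
    z <- occ$z[idx] + stats::runif(length(idx), -0.125, 0.125)
    cls <- rep(1L, length(idx))
    # ground returns on a dense grid (class 2), z ~ 0 above terrain
    gx <- seq(geom$center_x - h, geom$center_x + h, by = 0.25)
    gy <- seq(geom$center_y - h, geom$center_y + h, by = 0.25)
    gg <- expand.grid(x = gx, y = gy)
    x <- c(x, gg$x); y <- c(y, gg$y)
    z <- c(z, abs(stats::rnorm(nrow(gg), 0, 0.01)))
    cls <- c(cls, rep(2L, nrow(gg)))
    if (noise_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, noise_sd)
      y <- y + stats::rnorm(length(y), 0, noise_sd)
      z <- z + stats::rnorm(length(z), 0, noise_sd)
    }
    z_abs <- z + scene$spec$ground_slope * x
    point_cloud(x, y, z_abs, return_number = 1L, classification = cls)
  })
}

# per-column structure of sub-canopy occupied voxels for top-down ALS
# interception: matrix Z[column, rank] of occupied voxel centre heights
# sorted top-down, plus the per-column occupied count
column_structure <- function(scene, z_top = 12) {
  ex <- scene$spec$extent_x; ey <- scene$spec$extent_y
  nx <- as.integer(round(ex / 0.5)); ny <- as.integer(round(ey / 0.5))
  occ <- scene$occupied
  occ <- occ[occ$z < z_top & occ$kind != "crown", , drop = FALSE]
  ci <- pmin(nx - 1L, as.integer(base::floor(occ$x / 0.5)))
  cj <- pmin(ny - 1L, as.integer(base::floor(occ$y / 0.5)))
  col <- ci + nx * cj + 1L
  ord <- order(col, -occ$z)
  col_o <- col[ord]; z_o <- occ$z[ord]
  m <- tabulate(col_o, nbins = nx * ny)
  max_m <- max(m, 1L)
  Z <- matrix(NA_real_, nrow = nx * ny, ncol = max_m)
  if (length(col_o) > 0) {
    rank_in_col <- sequence(rle(col_o)$lengths)
    Z[cbind(col_o, rank_in_col)] <- z_o
  }
  list(Z = Z, m = m, nx = nx, ny = ny)
}

#' Sample an ALS-like first-return cloud from a scene
#'
#' Emulates a discrete-return airborne acquisition viewed from above.
#' Pulses form a Poisson process over the scene; each pulse is
#' intercepted by every crown it crosses with probability
#' `1 - canopy_transmission` (dense `beech_like` canopies transmit less
#' than open `pine_like` ones by default), otherwise it penetrates to
#' the sub-canopy column of occupied voxels, where each voxel crossed
#' top-down intercepts it with probability `p_understory`; pulses
#' reaching the bottom return from the ground (class 2). Only first
#' returns are emitted.
#'
#' @param scene A [generate_scene()] result.
#' @param pulse_density Pulses per square metre, default 2.
#' @param canopy_transmission Per-crown transmission probability in
#'   `(0, 1]`; default is the scene's stand-type value.
#' @param p_understory Per-voxel interception probability of sub-canopy
#'   occupied voxels, default 0.35.
#' @param seed Seed for the sampling draw.
#' @return A [point_cloud()] of first returns in absolute coordinates.
#' @export
sample_als <- function(scene, pulse_density = 2, canopy_transmission = NULL,
                       p_understory = 0.35, seed = 1L) {
  stopifnot(inherits(scene, "forest_scene"))
  if (is.null(canopy_transmission)) canopy_transmission <- scene$transmission
  if (!(canopy_transmission > 0 && canopy_transmission <= 1))
    stop("canopy_transmission must lie in (0, 1]", call. = FALSE)
  with_seed(seed, {
    ex <- scene$spec$extent_x; ey <- scene$spec$extent_y
    n <- stats::rpois(1, pulse_density * ex * ey)
    px <- stats::runif(n, 0, ex); py <- stats::runif(n, 0, ey)
    crossings <- integer(n)
    surf_z <- rep(-Inf, n)
    st <- scene$stems
    for (s in seq_len(nrow(st))) {
      d2 <- (px - st$x[s])^2 + (py - st$y[s])^2
      r2 <- st$crown_radius[s]^2
      hit <- d2 < r2
      if (!any(hit)) next
      crossings[hit] <- crossings[hit] + 1L
      zc <- (st$crown_base[s] + st$crown_top[s]) / 2
      rz <- (st$crown_top[s] - st$crown_base[s]) / 2
      zs <- zc + rz * sqrt(1 - d2[hit] / r2)
      surf_z[hit] <- pmax(surf_z[hit], zs)
    }
    canopy_hit <- crossings > 0L &
      stats::runif(n) < 1 - canopy_transmission^crossings
    z <- numeric(n)
    cls <- rep(1L, n)
    # canopy returns: crown surface with a little penetration depth
    depth <- pmin(stats::rexp(sum(canopy_hit), 2), 2)
    z[canopy_hit] <- pmax(surf_z[canopy_hit] - depth,
                          scene$spec$canopy_base)
    # remaining pulses test the sub-canopy occupied columns top-down
    rest <- which(!canopy_hit)
    cs <- column_structure(scene, z_top = 12)
    ci <- pmin(cs$nx - 1L, as.integer(base::floor(px[rest] / 0.5)))
    cj <- pmin(cs$ny - 1L, as.integer(base::floor(py[rest] / 0.5)))
    col <- ci + cs$nx * cj + 1L
    g <- stats::rgeom(length(rest), p_understory) + 1L
    has_under <- g <= cs$m[col]
    uz <- cs$Z[cbind(col[has_under], g[has_under])] +
      stats::runif(sum(has_under), -0.125, 0.125)
    z[rest[has_under]] <- uz
    gr <- rest[!has_under]
    z[gr] <- abs(stats::rnorm(length(gr), 0, 0.02))
    cls[gr] <- 2L
    z_abs <- z + scene$spec$ground_slope * px
    point_cloud(px, py, z_abs, return_number = 1L, classification = cls)
  })
}
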
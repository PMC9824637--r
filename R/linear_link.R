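# "Linear-link" scene family: synthetic plots engineered so that the
# true upper-understory density is an exact known linear function of
# the expected HM_1_3 ALS metric, for parameter-recovery experiments.
#
# Geometry per plot (27 x 27 m):
#   - a lower foliage layer [2, 2 + w] m of clumped voxels (fill
#     `lu_fill`); its thickness w varies across plots and drives the
#     expected mean height of sub-H/3 ALS returns (HM_1_3);
#   - a sparse emergent canopy (~21.5 m crowns) pinning the maximum
#     height near 22 m, hence the one-third boundary near 7.3 m;
#   - an upper foliage layer confined to [7.5, 10) m - entirely above
#     any realizable H/3 - whose fill realizes the response
#       true UU PDI = beta * E[HM_1_3] + intercept + eps,
#     without feeding back on the predictor.
#
# E[HM_1_3] is computed exactly from the realized lower-layer geometry
# via the top-down per-voxel interception model used by sample_als().

#' Expected HM_1_3 of a scene under the ALS interception model
#'
#' For every 0.5 m column, occupied voxels intercept a penetrating pulse
#' top-down with probability `p_understory` each, giving voxel `j` (from
#' the top) interception probability `p (1-p)^(j-1)`. The expected mean
#' height of returns below `band_top` is the probability-weighted mean
#' of the corresponding voxel centres - the large-sample limit of the
#' measured HM_1_3, computed from geometry alone.
#'
#' @param occupied Data frame of occupied voxel centres (`x`, `y`, `z`).
#' @param extent_x,extent_y Scene extent (m).
#' @param p_understory Per-voxel interception probability.
#' @param band_top Upper bound (m) of the height band (nominal H/3).
#' @param band_bottom Lower bound (m), default 0.5 (the ALS floor).
#' @return Expected mean return height (m), or `NA` if no voxel lies in
#'   the band.
#' @export
expected_hm13 <- function(occupied, extent_x, extent_y, p_understory = 0.35,
                          band_top = 7.3, band_bottom = 0.5) {
  if (nrow(occupied) == 0) return(NA_real_)
  nx <- as.integer(round(extent_x / 0.5))
  ny <- as.integer(round(extent_y / 0.5))
  ci <- pmin(nx - 1L, as.integer(base::floor(occupied$x / 0.5)))
  cj <- pmin(ny - 1L, as.integer(base::floor(occupied$y / 0.5)))
  col <- ci + nx * cj + 1L
  ord <- order(col, -occupied$z)
  col_o <- col[ord]; z_o <- occupied$z[ord]
  rank_in_col <- sequence(rle(col_o)$lengths)
  w <- p_understory * (1 - p_understory)^(rank_in_col - 1)
  sel <- z_o >= band_bottom & z_o < band_top
  if (!any(sel)) return(NA_real_)
  sum(w[sel] * z_o[sel]) / sum(w[sel])
}

# one linear-link plot scene; lower layer only, response layer added by
# the caller once the response value is known
linear_link_base_scene <- function(w, lu_fill, extent = 27) {
  nx <- as.integer(round(extent / 0.5))
  k_hi <- 8L + as.integer(round(w / 0.25))
  lu <- voxel_df(clumped_voxels(nx, nx, k_lo = 9L, k_hi = k_hi,
                                fill = lu_fill), "foliage")
  n_em <- 3L
  stems <- data.frame(
    x = stats::runif(n_em, 2, extent - 2),
    y = stats::runif(n_em, 2, extent - 2),
    dbh_cm = stats::runif(n_em, 40, 60),
    crown_top = 21.3 + stats::runif(n_em, 0, 0.6),
    crown_base = 20, crown_radius = 2.2
  )
  spec <- scene_spec(extent_x = extent, extent_y = extent,
                     stand_type = "pine_like", stem_density = 0,
                     canopy_base = 20, canopy_top = 22,
                     understory_intensity_LU = 0,
                     understory_intensity_UU = 0, seed = 0L)
  structure(list(spec = spec, stems = stems,
                 field_trees = stems[, c("x", "y", "dbh_cm")],
                 occupied = lu, transmission = 0.5),
            class = "forest_scene")
}

#' Simulate a linear-link plot study
#'
#' Generates `n_plots` synthetic plots in "linear-link" mode: the true
#' upper-understory (UU) density of plot *i* is
#' `beta * x_i + intercept + eps_i`, where `x_i` is the exact expected
#' HM_1_3 of the plot's lower foliage layer ([expected_hm13()]) and
#' `eps_i` is Gaussian noise. The realized response is clipped to the
#' feasible occupancy range (truth can reach at most 0.5, since the
#' response layer occupies the upper half of the 5-10 m stratum). The
#' defaults span true UU densities of roughly 0.05-0.5 across plots.
#'
#' @param n_plots Number of plots, default 24.
#' @param beta,intercept True linear coefficients.
#' @param noise_sd Standard deviation of `eps` (PDI units), default 0.04.
#' @param lu_fill Voxel fill of the lower layer, default 0.45.
#' @param w_range Range of lower-layer thickness across plots (m).
#' @param p_understory Per-voxel ALS interception probability.
#' @param seed Master seed; plot-level draws derive from it.
#' @return An object of class `linear_link_study`: `plots` (data frame
#'   `plot_id`, `w`, `hm13_true`, `uu_true_pdi`, `lu_true_pdi`),
#'   `scenes` (list of `forest_scene`), `true_slope`, `true_intercept`,
#'   `p_understory`.
#' @export
simulate_linear_link_study <- function(n_plots = 24, beta = 0.28,
                                       intercept = -0.66, noise_sd = 0.04,
                                       lu_fill = 0.45, w_range = c(1, 3),
                                       p_understory = 0.35, seed = 1L) {
  ws <- seq(w_range[1], w_range[2], length.out = n_plots)
  scenes <- vector("list", n_plots)
  rows <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    with_seed(seed + 101L * i, {
      sc <- linear_link_base_scene(ws[i], lu_fill)
      x_i <- expected_hm13(sc$occupied, 27, 27, p_understory)
      y_i <- beta * x_i + intercept + stats::rnorm(1, 0, noise_sd)
      y_i <- min(max(y_i, 0.005), 0.5)
      uu <- voxel_df(clumped_voxels(54L, 54L, k_lo = 31L, k_hi = 40L,
                                    fill = 2 * y_i), "foliage")
      sc$occupied <- rbind(sc$occupied, uu)
      scenes[[i]] <- sc
      rows[[i]] <- data.frame(
        plot_id = sprintf("plot_%02d", i), w = ws[i], hm13_true = x_i,
        uu_true_pdi = nrow(uu) / (54 * 54 * 20),
        lu_true_pdi = sum(sc$occupied$z >= 2 & sc$occupied$z < 5) /
          (54 * 54 * 12),
        stringsAsFactors = FALSE)
    })
  }
  structure(list(plots = do.call(rbind, rows), scenes = scenes,
                 true_slope = beta, true_intercept = intercept,
                 p_understory = p_understory),
            class = "linear_link_study")
}

#' @export
print.linear_link_study <- function(x, ...) {
  cat(sprintf(
    "<linear_link_study> %d plots, true slope %.3f, true UU PDI [%.3f, %.3f]\n",
    nrow(x$plots), x$true_slope, min(x$plots$uu_true_pdi),
    max(x$plots$uu_true_pdi)))
  invisible(x)
}

#' ALS metrics and true response for a linear-link study
#'
#' Samples an ALS cloud for every plot of a [simulate_linear_link_study()],
#' runs [prepare_als()] and [compute_metrics()], and joins the true UU
#' density - the table a recovery fit consumes.
#'
#' @param study A `linear_link_study`.
#' @param pulse_density Pulses per square metre, default 4.
#' @param seed Master seed for the sampling draws.
#' @return Data frame: `plot_id`, `UU` (true PDI), the 17 metrics.
#' @export
linear_link_metrics <- function(study, pulse_density = 4, seed = 1L) {
  rows <- lapply(seq_along(study$scenes), function(i) {
    cloud <- sample_als(study$scenes[[i]], pulse_density = pulse_density,
                        p_understory = study$p_understory,
                        seed = seed + 577L * i)
    met <- compute_metrics(prepare_als(cloud),
                           unit_id = study$plots$plot_id[i])
    cbind(data.frame(plot_id = study$plots$plot_id[i],
                     UU = study$plots$uu_true_pdi[i],
                     stringsAsFactors = FALSE),
          met[, als_metric_names()])
  })
  do.call(rbind, rows)
}
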
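make_coverage_cloud <- function(seed = 1, extent = 100, density = 3) {
  set.seed(seed)
  n <- extent * extent * density
  point_cloud(runif(n, 0, extent), runif(n, 0, extent),
              c(runif(n / 2, 0, 0.4), runif(n / 2, 0.5, 18)),
              classification = c(rep(2L, n / 2), rep(1L, n / 2)))
}

test_that("per-cell metrics equal compute_metrics on the cell's points", {
  cloud <- make_coverage_cloud(seed = 101)
  cells <- grid_metrics(cloud, cell_size = 25, min_points = 10)
  expect_true(all(c("cell_x", "cell_y", als_metric_names()) %in%
                    names(cells)))
  expect_equal(nrow(cells), 16)  # 100 m / 25 m in each direction
  cx <- cells$cell_x[3]; cy <- cells$cell_y[3]
  keep <- cloud$x >= cx & cloud$x < cx + 25 &
    cloud$y >= cy & cloud$y < cy + 25
  direct <- compute_metrics(
    prepare_als(understoRy:::as_point_cloud(cloud[keep, ])))
  for (nm in als_metric_names())
    expect_equal(cells[[nm]][3], direct[[nm]], label = nm)
})

test_that("sparse cells fall below min_points and are dropped", {
  set.seed(102)
  # one dense cell, one cell with too few prepared points
  dense <- point_cloud(runif(200, 0, 25), runif(200, 0, 25),
                       runif(200, 1, 15))
  sparse <- point_cloud(runif(5, 25, 50), runif(5, 0, 25),
                        runif(5, 1, 15))
  cells <- grid_metrics(understoRy:::as_point_cloud(rbind(dense, sparse)),
                        cell_size = 25, min_points = 10)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$cell_x, 0)
})

test_that("uniform clouds give equal cell HMEANs within sampling error", {
  cloud <- make_coverage_cloud(seed = 103, density = 6)
  cells <- grid_metrics(cloud, cell_size = 25)
  se <- sd(cells$HMEAN) / sqrt(nrow(cells))
  expect_true(all(abs(cells$HMEAN - mean(cells$HMEAN)) <
                    3 * sd(cells$HMEAN) + 1e-9))
  # theoretical mean of U(0.5, 18) heights
  expect_lt(abs(mean(cells$HMEAN) - (0.5 + 18) / 2), 0.2)
})

test_that("predict_map builds the raster, clamps, and flags NoData", {
  cloud <- make_coverage_cloud(seed = 104)
  cells <- grid_metrics(cloud, cell_size = 25)
  d <- make_fit_data(cells)
  m <- understory_model(UU ~ HM_1_3, d)
  r <- predict_map(cells, m)
  expect_s3_class(r, "prediction_raster")
  expect_equal(c(r$n_rows, r$n_cols), c(4, 4))
  expect_true(all(r$values >= 0 & r$values <= 1, na.rm = TRUE))
  # a constant (zero-slope) model paints every populated cell alike
  d0 <- d; d0$UU <- 0.3
  suppressWarnings(m0 <- understory_model(UU ~ HM_1_3, d0))
  r0 <- predict_map(cells, m0)
  expect_equal(unique(as.vector(r0$values)), 0.3, tolerance = 1e-9)
  # clamp boundary: force predictions below zero
  dneg <- d; dneg$UU <- -0.05
  suppressWarnings(mneg <- understory_model(UU ~ HM_1_3, dneg))
  expect_equal(unique(as.vector(predict_map(cells, mneg)$values)), 0)
  # populated + NoData tiles the raster
  few <- predict_map(cells[1:5, ], m)
  expect_equal(sum(!is.na(few$values)) + sum(is.na(few$values)),
               few$n_rows * few$n_cols)
})

test_that("rasters are deterministic and round-trip through ESRI ASCII", {
  cloud <- make_coverage_cloud(seed = 105)
  cells <- grid_metrics(cloud, cell_size = 25)
  m <- understory_model(UU ~ HM_1_3, make_fit_data(cells))
  r1 <- predict_map(cells, m)
  r2 <- predict_map(grid_metrics(make_coverage_cloud(seed = 105),
                                 cell_size = 25), m)
  expect_identical(r1$values, r2$values)
  p1 <- withr::local_tempfile(fileext = ".asc")
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_raster_asc(r1, p1); write_raster_asc(r2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  hdr <- readLines(p1, n = 6)
  expect_match(hdr[1], "^ncols 4$")
  expect_match(hdr[6], "NODATA_value")
  df <- as.data.frame(r1)
  expect_equal(nrow(df), 16)
  expect_equal(sort(unique(df$cell_x)), c(0, 25, 50, 75))
})

test_that("predictions track a known spatial understory gradient", {
  # a 200 x 100 m coverage built from 25 m tiles whose upper-understory
  # intensity ramps along x; per-tile truth is exact from the scenes
  tiles <- expand.grid(ix = 0:7, iy = 0:3)
  tiles$uu <- 0.1 + 0.45 * tiles$ix / 7
  clouds <- list(); truth <- numeric(nrow(tiles))
  for (t in seq_len(nrow(tiles))) {
    sc <- generate_scene(scene_spec(extent_x = 25, extent_y = 25,
                                    stand_type = "pine_like",
                                    stem_density = 200,
                                    understory_intensity_LU = 0.25,
                                    understory_intensity_UU = tiles$uu[t],
                                    seed = 700 + t))
    truth[t] <- scene_truth_pdi(sc)$true_pdi[4]
    a <- sample_als(sc, pulse_density = 2, seed = 800 + t)
    a$x <- a$x + 25 * tiles$ix[t]
    a$y <- a$y + 25 * tiles$iy[t]
    clouds[[t]] <- a
  }
  cov <- understoRy:::as_point_cloud(do.call(rbind, clouds))
  cells <- grid_metrics(cov, cell_size = 25)
  expect_equal(nrow(cells), 32)
  ord <- order(cells$cell_y, cells$cell_x)
  tord <- order(tiles$iy, tiles$ix)
  d <- cells[ord, ]
  d$UU <- truth[tord]
  m <- understory_model(UU ~ HM_1_3, d)
  r <- predict_map(d, m)
  pred_df <- as.data.frame(r)
  pred_df <- pred_df[order(pred_df$cell_y, pred_df$cell_x), ]
  expect_gt(cor(pred_df$value, truth[tord]), 0.7)
})
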
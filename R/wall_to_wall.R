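#' Compute ALS metrics on a regular grid
#'
#' Tiles the ALS coverage into square cells (25 m by default, the
#' resolution of the wall-to-wall maps) and computes the full metric set
#' per cell. Each cell's points are passed through [prepare_als()] and
#' [compute_metrics()] exactly as a plot would be, so per-cell OGP uses
#' the cell's own pre-threshold first returns. The grid origin is
#' snapped to multiples of `cell_size`, making the tiling independent of
#' the cloud's bounding box. Cells with fewer than `min_points` prepared
#' points are dropped (their metrics would be unreliable).
#'
#' @param cloud A height-normalized [point_cloud()] covering the area
#'   (all returns; first returns are selected internally).
#' @param cell_size Cell edge (m), default 25.
#' @param min_points Minimum prepared points per retained cell,
#'   default 10.
#' @param cap,floor Height window passed to [prepare_als()].
#' @return Data frame: `cell_x`, `cell_y` (cell lower-left corners),
#'   `unit_id`, and the 17 metric columns; one row per retained cell.
#' @export
grid_metrics <- function(cloud, cell_size = 25, min_points = 10,
                         cap = 22, floor = 0.5) {
  fr <- cloud[cloud$return_number == 1L, , drop = FALSE]
  if (nrow(fr) == 0)
    return(cbind(data.frame(cell_x = numeric(), cell_y = numeric(),
                            unit_id = character()),
                 stats::setNames(as.data.frame(
                   matrix(numeric(), 0, 17)), als_metric_names())))
  ox <- base::floor(min(fr$x) / cell_size) * cell_size
  oy <- base::floor(min(fr$y) / cell_size) * cell_size
  ci <- as.integer(base::floor((fr$x - ox) / cell_size))
  cj <- as.integer(base::floor((fr$y - oy) / cell_size))
  key <- paste(ci, cj, sep = "_")
  rows <- lapply(split(seq_len(nrow(fr)), key), function(idx) {
    sub <- as_point_cloud(fr[idx, , drop = FALSE])
    prepared <- prepare_als(sub, cap = cap, floor = floor)
    if (nrow(prepared) < min_points) return(NULL)
    cx <- ox + ci[idx[1]] * cell_size
    cy <- oy + cj[idx[1]] * cell_size
    cbind(data.frame(cell_x = cx, cell_y = cy),
          compute_metrics(prepared,
                          unit_id = sprintf("cell_%g_%g", cx, cy)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(grid_metrics(point_cloud(), cell_size, min_points))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cell_y, out$cell_x), , drop = FALSE]
}

#' Predict an understory density raster
#'
#' Applies a fitted [understory_model()] to per-cell metrics from
#' [grid_metrics()], producing a regular raster of predicted PDI. Cells
#' absent from `cell_metrics` (too few points) or with missing predictor
#' values become NoData. Raw linear predictions may leave `[0, 1]`; they
#' are clamped by default since PDI is a fraction.
#'
#' @param cell_metrics Output of [grid_metrics()].
#' @param model An [understory_model()].
#' @param clamp Clamp predictions to `[0, 1]` (default `TRUE`).
#' @param cell_size Cell edge (m), default 25.
#' @param crs Optional coordinate reference identifier stored with the
#'   raster (e.g. an EPSG string); purely pass-through.
#' @return An object of class `prediction_raster`: `values` is an
#'   `n_rows x n_cols` matrix (row 1 = southernmost row), `NA` = NoData;
#'   plus `origin_x`, `origin_y`, `cell_size`, `layer_name`, `crs`.
#' @export
predict_map <- function(cell_metrics, model, clamp = TRUE, cell_size = 25,
                        crs = "") {
  stopifnot(inherits(model, "understory_model"))
  if (nrow(cell_metrics) == 0)
    stop("cell_metrics is empty; nothing to predict", call. = FALSE)
  preds <- predict(model, newdata = cell_metrics, clamp = clamp)
  ox <- min(cell_metrics$cell_x)
  oy <- min(cell_metrics$cell_y)
  n_cols <- as.integer((max(cell_metrics$cell_x) - ox) / cell_size) + 1L
  n_rows <- as.integer((max(cell_metrics$cell_y) - oy) / cell_size) + 1L
  vals <- matrix(NA_real_, nrow = n_rows, ncol = n_cols)
  i <- as.integer(round((cell_metrics$cell_y - oy) / cell_size)) + 1L
  j <- as.integer(round((cell_metrics$cell_x - ox) / cell_size)) + 1L
  vals[cbind(i, j)] <- preds
  structure(list(origin_x = ox, origin_y = oy, cell_size = cell_size,
                 n_cols = n_cols, n_rows = n_rows, values = vals,
                 crs = crs, layer_name = model$response_name),
            class = "prediction_raster")
}

#' @export
print.prediction_raster <- function(x, ...) {
  filled <- sum(!is.na(x$values))
  cat(sprintf(
    "<prediction_raster> %s: %d x %d cells of %g m (%d populated)\n",
    x$layer_name, x$n_rows, x$n_cols, x$cell_size, filled))
  if (filled > 0)
    cat(sprintf("  predicted PDI range [%.3f, %.3f]\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.prediction_raster <- function(x, ...) {
  idx <- which(!is.na(x$values) | TRUE, arr.ind = TRUE)
  data.frame(
    cell_x = x$origin_x + (idx[, 2] - 1L) * x$cell_size,
    cell_y = x$origin_y + (idx[, 1] - 1L) * x$cell_size,
    value = as.vector(x$values[idx]),
    layer = x$layer_name
  )
}

#' @export
plot.prediction_raster <- function(x, ...) {
  graphics::image(
    x$origin_x + (seq_len(x$n_cols) - 0.5) * x$cell_size,
    x$origin_y + (seq_len(x$n_rows) - 0.5) * x$cell_size,
    t(x$values), xlab = "x (m)", ylab = "y (m)",
    main = sprintf("predicted %s PDI", x$layer_name), ...)
  invisible(x)
}

#' Write a prediction raster as an ESRI ASCII grid
#'
#' Plain-text raster format readable by GIS software (GDAL `AAIGrid`).
#' NoData cells are written as `nodata` (default -9999).
#'
#' @param raster A [predict_map()] result.
#' @param path Output path (conventionally `.asc`).
#' @param nodata NoData sentinel value.
#' @return `path`, invisibly.
#' @export
write_raster_asc <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "prediction_raster"))
  v <- raster$values
  v[is.na(v)] <- nodata
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.6f\nyllcorner %.6f\ncellsize %.6f\nNODATA_value %g\n",
    raster$n_cols, raster$n_rows, raster$origin_x, raster$origin_y,
    raster$cell_size, nodata)
  writeChar(hdr, con, eos = NULL)
  for (i in rev(seq_len(raster$n_rows)))  # top row first
    writeChar(paste0(paste(formatC(v[i, ], format = "g", digits = 8),
                           collapse = " "), "\n"), con, eos = NULL)
  invisible(path)
}
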
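#' Names of the 17 ALS metrics
#'
#' Twelve height-based metrics (mean, relative mean, standard deviation,
#' coefficient of variation, skewness and kurtosis of first-return
#' heights, plus the mean and standard deviation within each third of
#' the height range) and five density-based metrics (fraction of
#' non-ground first returns, total first-return count, and the point
#' proportions of the three thirds).
#'
#' @return Character vector of the metric column names in canonical order.
#' @export
als_metric_names <- function() {
  c("HMEAN", "RHMEAN", "SDH", "HCV", "HS", "HK",
    "HM_1_3", "HM_2_3", "HM_3_3", "SD_1_3", "SD_2_3", "SD_3_3",
    "OGP", "PTN", "PP_1_3", "PP_2_3", "PP_3_3")
}

#' Prepare an ALS cloud for metric computation
#'
#' Keeps first returns only, removes points higher than `cap` (22 m by
#' default, so that ALS and TLS describe a comparable height range) and
#' applies a lower height threshold (0.5 m). The fraction of non-ground
#' first returns (OGP) is recorded *before* the lower threshold is
#' applied - its denominator is the total number of first returns,
#' ground echoes included - and carried along as an attribute consumed
#' by [compute_metrics()]. Non-ground means LAS class != 2 when a ground
#' classification is present, otherwise height above the threshold.
#'
#' @param cloud A height-normalized [point_cloud()].
#' @param cap Upper height cut (m), default 22.
#' @param floor Lower height threshold (m), default 0.5.
#' @return A `point_cloud` of prepared first returns, with attributes
#'   `n_first_total` and `ogp`.
#' @export
prepare_als <- function(cloud, cap = 22, floor = 0.5) {
  fr <- cloud[cloud$return_number == 1L, , drop = FALSE]
  n_first <- nrow(fr)
  ogp <- NA_real_
  if (n_first > 0) {
    nonground <- if (any(fr$classification == 2L))
      fr$classification != 2L else fr$z > floor
    ogp <- sum(nonground) / n_first
  }
  out <- as_point_cloud(fr[fr$z >= floor & fr$z <= cap, , drop = FALSE])
  attr(out, "n_first_total") <- n_first
  attr(out, "ogp") <- ogp
  attr(out, "prepared") <- TRUE
  out
}

# moment-based sample skewness and (non-excess) kurtosis
moment_skew <- function(z) {
  n <- length(z); m <- mean(z)
  m2 <- mean((z - m)^2)
  if (n < 2 || m2 == 0) return(NA_real_)
  mean((z - m)^3) / m2^1.5
}
moment_kurt <- function(z) {
  n <- length(z); m <- mean(z)
  m2 <- mean((z - m)^2)
  if (n < 2 || m2 == 0) return(NA_real_)
  mean((z - m)^4) / m2^2
}

#' Compute the 17 ALS metrics for one spatial unit
#'
#' Operates on a cloud prepared by [prepare_als()] (first returns within
#' the 0.5-22 m window). Height metrics: `HMEAN` (mean height), `RHMEAN`
#' (mean / maximum height), `SDH` (sample standard deviation), `HCV`
#' (`SDH/HMEAN`), `HS`/`HK` (moment skewness and non-excess kurtosis).
#' The height range is split into thirds at `H/3` and `2H/3`, where `H`
#' is the unit's maximum prepared height (at most the 22 m cap);
#' `HM_b`/`SD_b` are the mean and standard deviation within band `b`
#' (bands `[floor, H/3)`, `[H/3, 2H/3)`, `[2H/3, H]`; the top band is
#' closed so the highest point counts once) and `PP_b` the band point
#' proportions, which sum to one. `PTN` is the number of prepared
#' points; `OGP` the pre-threshold non-ground fraction recorded by
#' [prepare_als()].
#'
#' Empty units yield missing metrics; dispersion metrics need at least
#' two points (per band for `SD_b`).
#'
#' @param cloud A `point_cloud` from [prepare_als()].
#' @param unit_id Identifier (plot or grid-cell id) for the output row.
#' @return One-row data frame: `unit_id` plus the columns of
#'   [als_metric_names()].
#' @export
compute_metrics <- function(cloud, unit_id = "unit") {
  out <- as.list(rep(NA_real_, 17))
  names(out) <- als_metric_names()
  out$OGP <- if (!is.null(attr(cloud, "ogp"))) attr(cloud, "ogp") else NA_real_
  z <- cloud$z
  n <- length(z)
  out$PTN <- n
  if (n > 0) {
    H <- max(z)
    out$HMEAN <- mean(z)
    out$RHMEAN <- if (H > 0) out$HMEAN / H else NA_real_
    out$SDH <- if (n >= 2) stats::sd(z) else NA_real_
    out$HCV <- if (n >= 2 && out$HMEAN > 0) out$SDH / out$HMEAN else NA_real_
    out$HS <- moment_skew(z)
    out$HK <- moment_kurt(z)
    b1 <- H / 3; b2 <- 2 * H / 3
    bands <- list(z[z < b1], z[z >= b1 & z < b2], z[z >= b2])
    for (b in 1:3) {
      zb <- bands[[b]]
      out[[paste0("HM_", b, "_3")]] <-
        if (length(zb) > 0) mean(zb) else NA_real_
      out[[paste0("SD_", b, "_3")]] <-
        if (length(zb) >= 2) stats::sd(zb) else NA_real_
      out[[paste0("PP_", b, "_3")]] <- length(zb) / n
    }
  } else {
    out$PTN <- 0L
    out$PP_1_3 <- out$PP_2_3 <- out$PP_3_3 <- NA_real_
  }
  cbind(data.frame(unit_id = unit_id, stringsAsFactors = FALSE),
        as.data.frame(out))
}
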
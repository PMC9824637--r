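#' Screen candidate ALS predictors by Pearson correlation
#'
#' A metric enters the candidate set when its Pearson correlation with
#' the response is significant (two-sided test, `p < alpha`) and
#' `|r| > r_threshold` (0.7 by default). The absolute value is used so
#' that negatively associated metrics are not silently lost. No
#' multiplicity correction is applied. Constant columns are skipped with
#' a warning. Results are ordered by decreasing `|r|`.
#'
#' @param metrics Data frame holding metric columns (e.g. the output of
#'   [compute_metrics()] row-bound over plots).
#' @param response Numeric response vector (per-plot PDI), aligned with
#'   the rows of `metrics`.
#' @param r_threshold Absolute correlation threshold, default 0.7.
#' @param alpha Significance level of the correlation test, default 0.05.
#' @param candidates Columns to consider; defaults to the intersection of
#'   [als_metric_names()] with `names(metrics)`.
#' @return Character vector of selected metric names (may be empty),
#'   ordered by `|r|` descending, with the full screening table attached
#'   as attribute `"screening"` (`metric`, `r`, `p_value`, `selected`).
#' @export
screen_predictors <- function(metrics, response, r_threshold = 0.7,
                              alpha = 0.05, candidates = NULL) {
  if (is.null(candidates))
    candidates <- intersect(als_metric_names(), names(metrics))
  if (length(response) != nrow(metrics))
    stop("response length must match the number of metric rows", call. = FALSE)
  if (nrow(metrics) < 3)
    stop("need at least 3 plots to screen predictors", call. = FALSE)
  rows <- lapply(candidates, function(nm) {
    v <- metrics[[nm]]
    ok <- stats::complete.cases(v, response)
    if (sum(ok) < 3 || stats::sd(v[ok]) == 0 || stats::sd(response[ok]) == 0) {
      warning(sprintf("metric %s is constant or too sparse; skipped", nm),
              call. = FALSE)
      return(data.frame(metric = nm, r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(v[ok], response[ok], method = "pearson")
    data.frame(metric = nm, r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$selected <- !is.na(tab$r) & abs(tab$r) > r_threshold &
    tab$p_value < alpha
  tab <- tab[order(-abs(tab$r)), ]
  sel <- tab$metric[tab$selected]
  attr(sel, "screening") <- tab
  sel
}

#' Fit an understory density model from ALS metrics
#'
#' The central estimator: an ordinary least squares regression of a
#' plot-level understory density (TLS-derived PDI of the lower or upper
#' understory stratum) on ALS metrics, evaluated by leave-one-out
#' cross-validation (LOOCV). When the formula right-hand side is `.`,
#' predictors are chosen by [screen_predictors()]; naming metrics
#' explicitly (e.g. `UU ~ HM_1_3`) pins them, which is how a published
#' model is replicated on new data.
#'
#' Reported accuracy follows the standard protocol: adjusted R-squared
#' from the full-data fit; RMSE over the LOOCV held-out predictions; and
#' the normalized error `nRMSE = RMSE / (y_max - y_min)` with the range
#' taken over the observed response. LOOCV predictions are obtained
#' exactly through the hat-matrix identity
#' `e_(i) = e_i / (1 - h_ii)` (PRESS residuals), equivalent to n
#' explicit refits.
#'
#' @param formula Model formula, response on the left (a column of
#'   `data`), metrics or `.` on the right.
#' @param data Data frame with the response, metric columns, and
#'   optionally `plot_id`.
#' @param r_threshold,alpha Screening parameters, used when the
#'   right-hand side is `.` (see [screen_predictors()]).
#' @param max_predictors In screening mode, keep at most this many
#'   screened metrics (by decreasing `|r|`), default 2. Plot-calibrated
#'   understory models are deliberately parsimonious: correlated metric
#'   suites would otherwise flood the fit. Ignored for explicit
#'   formulas.
#' @return An object of class `understory_model` with components
#'   `coefficients` (named vector), `coef_table` (term, estimate,
#'   std_error, t_value, p_value), `adjusted_r2`, `r2`, `loocv` (data
#'   frame plot_id/observed/predicted/residual), `rmse`, `nrmse`,
#'   `y_min`, `y_max`, `predictor_names`, `screening` (when screened),
#'   and the underlying `lm` fit.
#' @examples
#' set.seed(1)
#' d <- data.frame(HM_1_3 = runif(24, 2, 5))
#' d$UU <- 0.03 * d$HM_1_3 + 0.1 + rnorm(24, sd = 0.01)
#' m <- understory_model(UU ~ HM_1_3, d)
#' summary(m)
#' @export
understory_model <- function(formula, data, r_threshold = 0.7, alpha = 0.05,
                             max_predictors = 2L) {
  response_name <- all.vars(formula[[2]])
  if (!response_name %in% names(data))
    stop(sprintf("response '%s' not found in data", response_name),
         call. = FALSE)
  y <- data[[response_name]]
  rhs <- all.vars(formula[[3]])
  screening <- NULL
  if (identical(rhs, ".")) {
    sel <- screen_predictors(data, y, r_threshold, alpha)
    screening <- attr(sel, "screening")
    if (length(sel) == 0)
      stop(sprintf(
        "no metric passed screening (|r| > %g, p < %g) for %s",
        r_threshold, alpha, response_name), call. = FALSE)
    predictors <- utils::head(as.character(sel), max_predictors)
  } else {
    predictors <- setdiff(rhs, response_name)
    missing_p <- setdiff(predictors, names(data))
    if (length(missing_p) > 0)
      stop(sprintf("predictor column(s) missing from data: %s",
                   paste(missing_p, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(data)
  if (n <= length(predictors) + 1)
    stop("need more plots than predictors + 1 to fit", call. = FALSE)

  fml <- stats::reformulate(predictors, response = response_name)
  fit <- stats::lm(fml, data = data)
  qrr <- fit$qr
  if (qrr$rank < length(predictors) + 1L) {
    alias <- predictors[is.na(stats::coef(fit))[-1]]
    stop(sprintf("rank-deficient design; collinear predictor(s): %s",
                 paste(alias, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coef_table <- data.frame(term = rownames(ct), estimate = ct[, 1],
                           std_error = ct[, 2], t_value = ct[, 3],
                           p_value = ct[, 4], row.names = NULL,
                           stringsAsFactors = FALSE)

  # exact LOOCV through the hat matrix (PRESS residuals)
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  if (any(h > 1 - 1e-10))
    stop(sprintf(
      "LOOCV fold(s) rank-deficient (leverage 1) at row(s): %s",
      paste(which(h > 1 - 1e-10), collapse = ", ")), call. = FALSE)
  e_loo <- stats::residuals(fit) / (1 - h)
  pred_loo <- y - e_loo
  plot_id <- if (!is.null(data$plot_id)) data$plot_id else seq_len(n)
  loocv <- data.frame(plot_id = plot_id, observed = y,
                      predicted = as.numeric(pred_loo),
                      residual = as.numeric(e_loo),
                      stringsAsFactors = FALSE)
  rmse <- sqrt(mean(e_loo^2))
  y_min <- min(y); y_max <- max(y)
  structure(list(
    call = match.call(), formula = fml, response_name = response_name,
    predictor_names = predictors, coefficients = stats::coef(fit),
    coef_table = coef_table, r2 = sm$r.squared,
    adjusted_r2 = sm$adj.r.squared, loocv = loocv, rmse = rmse,
    nrmse = rmse / (y_max - y_min), y_min = y_min, y_max = y_max,
    n = n, screening = screening, lm = fit
  ), class = "understory_model")
}

#' Leave-one-out evaluation of a pinned metric set
#'
#' Convenience wrapper over [understory_model()] for a response vector
#' and explicit predictor names (no screening).
#'
#' @param metrics Data frame of metric columns (plus optional `plot_id`).
#' @param response Numeric response vector aligned with `metrics`.
#' @param predictors Character vector of metric names.
#' @param response_name Label for the response, default `"PDI"`.
#' @return An `understory_model` (see [understory_model()]).
#' @export
loocv_evaluate <- function(metrics, response, predictors,
                           response_name = "PDI") {
  d <- metrics
  d[[response_name]] <- response
  understory_model(stats::reformulate(predictors, response = response_name), d)
}

#' @export
print.understory_model <- function(x, ...) {
  cat(sprintf("<understory_model> %s ~ %s  (n = %d plots)\n",
              x$response_name, paste(x$predictor_names, collapse = " + "),
              x$n))
  print(x$coef_table, row.names = FALSE, digits = 4)
  cat(sprintf("adjusted R2 = %.3f; LOOCV RMSE = %.4f; nRMSE = %.1f%%\n",
              x$adjusted_r2, x$rmse, 100 * x$nrmse))
  invisible(x)
}

#' @export
summary.understory_model <- function(object, ...) {
  structure(list(model = object), class = "summary.understory_model")
}

#' @export
print.summary.understory_model <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$screening)) {
    cat("\nScreening (|r| > threshold and p < alpha):\n")
    print(m$screening, row.names = FALSE, digits = 3)
  }
  cat(sprintf("\nresponse range [%.3f, %.3f]; LOOCV residual SD %.4f\n",
              m$y_min, m$y_max, stats::sd(m$loocv$residual)))
  invisible(x)
}

#' @export
coef.understory_model <- function(object, ...) object$coefficients

#' Predict understory density for new spatial units
#'
#' Applies the fitted linear model to a table of metrics (plots or grid
#' cells). Predicted PDI is a fraction, so values are clamped to
#' `[0, 1]` unless `clamp = FALSE`. Rows with missing predictor values
#' yield `NA`.
#'
#' @param object An [understory_model()].
#' @param newdata Data frame containing the model's predictor columns.
#'   Omitted: returns full-fit fitted values.
#' @param clamp Clamp predictions into `[0, 1]` (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.understory_model <- function(object, newdata = NULL, clamp = TRUE,
                                     ...) {
  if (is.null(newdata)) {
    p <- stats::fitted(object$lm)
  } else {
    missing_p <- setdiff(object$predictor_names, names(newdata))
    if (length(missing_p) > 0)
      stop(sprintf("predictor column(s) missing from newdata: %s",
                   paste(missing_p, collapse = ", ")), call. = FALSE)
    X <- as.matrix(newdata[, object$predictor_names, drop = FALSE])
    p <- as.numeric(cbind(1, X) %*% object$coefficients)
  }
  if (clamp) p <- pmin(1, pmax(0, p))
  p
}

#' @export
fitted.understory_model <- function(object, ...) stats::fitted(object$lm)

#' Residuals of an understory model
#'
#' @param object An [understory_model()].
#' @param type `"response"` for full-fit residuals, `"loocv"` for
#'   held-out (PRESS) residuals.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
residuals.understory_model <- function(object,
                                       type = c("response", "loocv"), ...) {
  type <- match.arg(type)
  if (type == "loocv") object$loocv$residual else
    stats::residuals(object$lm)
}

#' Diagnostic plots for an understory model
#'
#' Two panels: observed versus LOOCV-predicted PDI with the 1:1 line,
#' and held-out residuals against predictions (for spotting curvature
#' or heteroscedasticity).
#'
#' @param x An [understory_model()].
#' @param ... Passed to the underlying plot calls.
#' @export
plot.understory_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  lim <- range(c(x$loocv$observed, x$loocv$predicted))
  graphics::plot(x$loocv$predicted, x$loocv$observed, pch = 16,
                 xlim = lim, ylim = lim,
                 xlab = "LOOCV predicted PDI", ylab = "observed PDI",
                 main = x$response_name, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(x$loocv$predicted, x$loocv$residual, pch = 16,
                 xlab = "LOOCV predicted PDI", ylab = "held-out residual",
                 main = "residuals", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Validate TLS density profiles against field tree counts
#'
#' Small trees (DBH below 9 cm) and intermediate trees (DBH 9-20 cm)
#' are the conventional field proxies of the lower (LU, 2-5 m) and
#' upper (UU, 5-10 m) understory. Per plot, trees are counted in the
#' two DBH classes and rank-correlated (Spearman) against the
#' corresponding stratum PDI.
#'
#' @param profiles Data frame of per-plot stratum PDI with columns
#'   `plot_id`, `stratum`, `pdi` (e.g. row-bound [pdi_by_stratum()]
#'   results).
#' @param field_trees Data frame with columns `plot_id`, `dbh_cm`.
#' @param dbh_small Upper DBH bound (exclusive) of the small-tree class,
#'   default 9 cm.
#' @param dbh_mid Upper DBH bound (inclusive) of the intermediate class,
#'   default 20 cm.
#' @return Data frame: `stratum`, `dbh_class`, `n_plots`,
#'   `spearman_rho`, `p_value`. Plots present in only one input are
#'   dropped with a warning.
#' @export
spearman_validation <- function(profiles, field_trees, dbh_small = 9,
                                dbh_mid = 20) {
  ids_p <- unique(profiles$plot_id)
  ids_f <- unique(field_trees$plot_id)
  common <- intersect(ids_p, ids_f)
  dropped <- setdiff(union(ids_p, ids_f), common)
  if (length(dropped) > 0)
    warning(sprintf("plot(s) present in only one table, excluded: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  if (length(common) < 3)
    stop("need at least 3 matched plots", call. = FALSE)
  count_class <- function(lo, hi) {
    vapply(common, function(id) {
      d <- field_trees$dbh_cm[field_trees$plot_id == id]
      sum(d >= lo & d < hi)
    }, numeric(1))
  }
  pairs <- list(
    LU = count_class(0, dbh_small),
    UU = count_class(dbh_small, dbh_mid + 1e-9)
  )
  labels <- c(LU = sprintf("DBH < %g cm", dbh_small),
              UU = sprintf("DBH %g-%g cm", dbh_small, dbh_mid))
  res <- lapply(names(pairs), function(st) {
    pdi <- vapply(common, function(id) {
      v <- profiles$pdi[profiles$plot_id == id & profiles$stratum == st]
      if (length(v) == 1) v else NA_real_
    }, numeric(1))
    ct <- suppressWarnings(
      stats::cor.test(pdi, pairs[[st]], method = "spearman", exact = FALSE))
    data.frame(stratum = st, dbh_class = labels[[st]],
               n_plots = length(common),
               spearman_rho = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
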
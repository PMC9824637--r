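make_metric_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(plot_id = sprintf("p%02d", seq_len(n)),
             HM_1_3 = runif(n, 2, 5), SD_1_3 = runif(n, 0.2, 1.5),
             HMEAN = runif(n, 5, 15), SDH = runif(n, 1, 4),
             stringsAsFactors = FALSE)
}

test_that("screening selects perfectly correlated metrics and orders by |r|", {
  d <- make_metric_table(12, seed = 61)
  sel <- screen_predictors(d, d$HM_1_3)
  expect_equal(sel[1], "HM_1_3")
  tab <- attr(sel, "screening")
  expect_equal(tab$r[tab$metric == "HM_1_3"], 1)
  # a negatively associated metric is kept through |r|
  sel2 <- screen_predictors(d, -d$SDH)
  expect_true("SDH" %in% sel2)
  expect_equal(attr(sel2, "screening")$r[
    attr(sel2, "screening")$metric == "SDH"], -1)
})

test_that("screening r values match the textbook Pearson formula", {
  d <- make_metric_table(5, seed = 62)
  set.seed(63)
  y <- runif(5)
  tab <- attr(screen_predictors(d, y, r_threshold = 0), "screening")
  for (nm in c("HM_1_3", "SD_1_3", "HMEAN", "SDH"))
    expect_equal(tab$r[tab$metric == nm], oracle_pearson(d[[nm]], y),
                 label = nm)
  expect_warning(
    screen_predictors(cbind(d, PTN = 7), y, candidates = "PTN"),
    "constant")
})

test_that("white-noise responses essentially never pass the 0.7 screen", {
  d <- make_metric_table(24, seed = 64)
  set.seed(65)
  hits <- 0
  for (r in 1:200) {
    y <- rnorm(24)
    hits <- hits + length(suppressWarnings(screen_predictors(d, y)))
  }
  # per-metric chance of |r| > 0.7 at n = 24 is ~ 1e-4
  expect_lte(hits, 2)
})

test_that("exact linear data is fitted exactly", {
  d <- make_metric_table(10, seed = 66)
  d$UU <- 0.03 * d$HM_1_3 + 0.1
  m <- suppressWarnings(understory_model(UU ~ HM_1_3, d))
  expect_equal(unname(coef(m)), c(0.1, 0.03), tolerance = 1e-10)
  expect_equal(m$adjusted_r2, 1, tolerance = 1e-10)
  expect_equal(m$rmse, 0, tolerance = 1e-10)
  expect_equal(m$nrmse, 0, tolerance = 1e-10)
})

test_that("coefficients match the normal-equations oracle", {
  d <- make_metric_table(6, seed = 67)
  set.seed(68)
  d$LU <- 0.2 + 0.05 * d$HM_1_3 + 0.03 * d$SD_1_3 + rnorm(6, 0, 0.02)
  m <- understory_model(LU ~ HM_1_3 + SD_1_3, d)
  beta <- oracle_ols(d[, c("HM_1_3", "SD_1_3")], d$LU)
  expect_equal(unname(coef(m)), as.numeric(beta), tolerance = 1e-10)
  expect_error(
    understory_model(LU ~ HM_1_3 + HM_1_3b,
                     transform(d, HM_1_3b = HM_1_3)),
    "collinear")
})

test_that("LOOCV equals n explicit refits", {
  for (npred in 1:3) {
    d <- make_metric_table(24, seed = 70 + npred)
    preds <- c("HM_1_3", "SD_1_3", "HMEAN")[seq_len(npred)]
    set.seed(80 + npred)
    d$UU <- 0.1 + as.matrix(d[preds]) %*% runif(npred, 0.01, 0.05) +
      rnorm(24, 0, 0.05)
    d$UU <- as.numeric(d$UU)
    m <- loocv_evaluate(d, d$UU, preds, response_name = "UU")
    naive <- oracle_loocv(d, "UU", preds)
    expect_equal(m$loocv$predicted, naive, tolerance = 1e-10)
    expect_equal(m$rmse, sqrt(mean((d$UU - naive)^2)), tolerance = 1e-10)
    expect_lte(m$adjusted_r2, m$r2)
  }
})

test_that("nRMSE follows its defining arithmetic", {
  # held-out predictions {0.5, 0.5} for observations {0, 1}:
  # RMSE = 0.5, range = 1, nRMSE = 0.5
  obs <- c(0, 1); pred <- c(0.5, 0.5)
  rmse <- sqrt(mean((obs - pred)^2))
  expect_equal(rmse / (max(obs) - min(obs)), 0.5)
  # and through the fitted object: perfect predictions give zero
  d <- make_metric_table(8, seed = 90)
  d$UU <- 0.02 * d$HM_1_3
  m <- suppressWarnings(understory_model(UU ~ HM_1_3, d))
  expect_equal(m$nrmse, 0, tolerance = 1e-10)
  expect_equal(m$y_min, min(d$UU))
  expect_equal(m$y_max, max(d$UU))
})

test_that("predict clamps to [0, 1] and checks for missing columns", {
  d <- make_metric_table(10, seed = 91)
  d$UU <- 0.03 * d$HM_1_3
  m <- suppressWarnings(understory_model(UU ~ HM_1_3, d))
  nd <- data.frame(HM_1_3 = c(-100, 100, 3))
  p <- predict(m, nd)
  expect_equal(p[1], 0)
  expect_equal(p[2], 1)
  expect_equal(predict(m, nd, clamp = FALSE)[3], 0.09, tolerance = 1e-12)
  expect_error(predict(m, data.frame(SD_1_3 = 1)), "HM_1_3")
  expect_true(is.na(predict(m, data.frame(HM_1_3 = NA_real_))))
})

test_that("model methods are coherent", {
  d <- make_metric_table(15, seed = 92)
  set.seed(93)
  d$UU <- 0.05 + 0.04 * d$HM_1_3 + rnorm(15, 0, 0.02)
  m <- understory_model(UU ~ HM_1_3, d)
  expect_s3_class(m, "understory_model")
  expect_named(coef(m), c("(Intercept)", "HM_1_3"))
  expect_equal(length(residuals(m)), 15)
  expect_equal(residuals(m, type = "loocv"), m$loocv$residual)
  expect_equal(fitted(m) + residuals(m), d$UU, ignore_attr = TRUE)
  expect_output(print(m), "understory_model")
  expect_output(print(summary(m)), "response range")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(m))
})

test_that("Spearman validation reproduces rank correlations with ties", {
  pdi <- do.call(rbind, lapply(1:10, function(i)
    data.frame(plot_id = sprintf("p%d", i), stratum = c("LU", "UU"),
               pdi = c(i / 10, (11 - i) / 10))))
  set.seed(94)
  trees <- do.call(rbind, lapply(1:10, function(i) {
    n_small <- i + (i %% 2)       # ties in counts
    n_mid <- 12 - i
    data.frame(plot_id = sprintf("p%d", i),
               dbh_cm = c(runif(n_small, 2, 8.9), runif(n_mid, 9, 20)))
  }))
  val <- spearman_validation(pdi, trees)
  lu_counts <- sapply(1:10, function(i) i + (i %% 2))
  uu_counts <- sapply(1:10, function(i) 12 - i)
  expect_equal(val$spearman_rho[val$stratum == "LU"],
               oracle_spearman(1:10 / 10, lu_counts))
  expect_equal(val$spearman_rho[val$stratum == "UU"],
               oracle_spearman((11 - 1:10) / 10, uu_counts))
  # UU pdi and intermediate counts are perfectly concordant here
  expect_equal(val$spearman_rho[val$stratum == "UU"], 1)
  # reversing the UU profile gives perfect discordance
  pdi_rev <- pdi
  pdi_rev$pdi[pdi_rev$stratum == "UU"] <- rep(1:10 / 10, each = 1)
  val_rev <- spearman_validation(pdi_rev, trees)
  expect_equal(val_rev$spearman_rho[val_rev$stratum == "UU"], -1)
  # mismatched plots are dropped with a warning
  expect_warning(
    spearman_validation(pdi, trees[trees$plot_id != "p1", ]), "excluded")
})
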
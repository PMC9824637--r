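# Independent oracles: deliberately naive implementations (explicit
# loops, textbook formulas) against which the package's vectorized
# paths are checked.

# per-point binning with an explicit loop
oracle_voxel_counts <- function(cloud, geom, dx = 0.5, dy = 0.5, dz = 0.25) {
  nx <- round(geom$square_side / dx)
  ny <- round(geom$square_side / dy)
  nz <- round((geom$z_max - geom$z_min) / dz)
  ox <- geom$center_x - geom$square_side / 2
  oy <- geom$center_y - geom$square_side / 2
  counts <- array(0L, dim = c(nx, ny, nz))
  for (p in seq_len(nrow(cloud))) {
    i <- floor((cloud$x[p] - ox) / dx) + 1
    j <- floor((cloud$y[p] - oy) / dy) + 1
    k <- floor((cloud$z[p] - geom$z_min) / dz) + 1
    counts[i, j, k] <- counts[i, j, k] + 1L
  }
  counts
}

# stratum PDI by direct counting over the vegetated array
oracle_stratum_pdi <- function(vegetated, z_origin, dz, z_low, z_high) {
  ks <- which(z_origin + (seq_len(dim(vegetated)[3]) - 1) * dz >= z_low - 1e-9 &
                z_origin + (seq_len(dim(vegetated)[3]) - 1) * dz < z_high - 1e-9)
  sum(vegetated[, , ks]) / (dim(vegetated)[1] * dim(vegetated)[2] * length(ks))
}

# the 17 metrics from first principles (textbook formulas; e1071 for
# the higher moments)
oracle_metrics <- function(z, ogp = NA_real_) {
  n <- length(z)
  H <- max(z)
  b1 <- H / 3; b2 <- 2 * H / 3
  band <- ifelse(z < b1, 1L, ifelse(z < b2, 2L, 3L))
  sd_or_na <- function(v) if (length(v) >= 2) sd(v) else NA_real_
  mean_or_na <- function(v) if (length(v) >= 1) mean(v) else NA_real_
  list(
    HMEAN = mean(z), RHMEAN = mean(z) / H, SDH = sd(z),
    HCV = sd(z) / mean(z),
    HS = e1071::skewness(z, type = 1),
    HK = e1071::kurtosis(z, type = 1) + 3,
    HM_1_3 = mean_or_na(z[band == 1]), HM_2_3 = mean_or_na(z[band == 2]),
    HM_3_3 = mean_or_na(z[band == 3]),
    SD_1_3 = sd_or_na(z[band == 1]), SD_2_3 = sd_or_na(z[band == 2]),
    SD_3_3 = sd_or_na(z[band == 3]),
    OGP = ogp, PTN = n,
    PP_1_3 = sum(band == 1) / n, PP_2_3 = sum(band == 2) / n,
    PP_3_3 = sum(band == 3) / n
  )
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# OLS through the normal equations
oracle_ols <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  solve(t(Xd) %*% Xd) %*% t(Xd) %*% y
}

# naive leave-one-out: n explicit refits
oracle_loocv <- function(data, response, predictors) {
  n <- nrow(data)
  fml <- reformulate(predictors, response = response)
  vapply(seq_len(n), function(i) {
    fit <- lm(fml, data = data[-i, ])
    unname(predict(fit, newdata = data[i, , drop = FALSE]))
  }, numeric(1))
}

# Spearman rho as Pearson correlation of (mid-)ranks
oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

# attach a synthetic linear response to a cell-metric table
make_fit_data <- function(cells, seed = 1) {
  set.seed(seed)
  d <- cells
  d$UU <- 0.03 * d$HM_1_3 + 0.05 + rnorm(nrow(d), 0, 0.01)
  d
}

# a seeded uniform random plot cloud already inside the default box
random_plot_cloud <- function(n, geom = plot_geometry(0, 0), seed = 1) {
  set.seed(seed)
  h <- geom$square_side / 2
  point_cloud(
    runif(n, geom$center_x - h, geom$center_x + h - 1e-9),
    runif(n, geom$center_y - h, geom$center_y + h - 1e-9),
    runif(n, geom$z_min, geom$z_max - 1e-9))
}
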
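test_that("prepare_als applies the cap, floor and first-return filter", {
  set.seed(31)
  z <- runif(2000, 0, 30)
  rn <- sample(1:2, 2000, replace = TRUE)
  cloud <- point_cloud(runif(2000), runif(2000), z, return_number = rn)
  prep <- prepare_als(cloud)
  brute <- sum(rn == 1L & z >= 0.5 & z <= 22)
  expect_equal(n_points(prep), brute)
  expect_true(all(prep$z >= 0.5 & prep$z <= 22))
  expect_true(all(prep$return_number == 1L))
  # boundary points named in the protocol
  edge <- prepare_als(point_cloud(1:2, 1:2, c(23, 0.3)))
  expect_equal(n_points(edge), 0)
})

test_that("OGP uses all first returns, before the height floor", {
  # 10 first returns, 4 of them ground-classified: OGP = 0.6 even though
  # the prepared cloud drops the low points
  cloud <- point_cloud(1:10, 1:10, c(0.1, 0.2, 0.05, 0.1, 2, 3, 4, 5, 6, 7),
                       classification = c(rep(2L, 4), rep(1L, 6)))
  prep <- prepare_als(cloud)
  expect_equal(attr(prep, "ogp"), 0.6)
  expect_equal(attr(prep, "n_first_total"), 10)
  expect_equal(compute_metrics(prep)$OGP, 0.6)
  # without classification: non-ground means above the floor
  cloud2 <- point_cloud(1:10, 1:10, c(0.1, 0.2, 0.3, 0.4, 2, 3, 4, 5, 6, 7))
  expect_equal(attr(prepare_als(cloud2), "ogp"), 0.6)
})

test_that("degenerate clouds give the expected metric values", {
  flat <- compute_metrics(prepare_als(point_cloud(1:5, 1:5, rep(6, 5))))
  expect_equal(flat$HMEAN, 6)
  expect_equal(flat$SDH, 0)
  expect_equal(flat$HCV, 0)
  expect_equal(flat$RHMEAN, 1)
  empty <- compute_metrics(prepare_als(point_cloud()))
  expect_equal(empty$PTN, 0)
  expect_true(is.na(empty$HMEAN) && is.na(empty$SDH))
  single <- compute_metrics(prepare_als(point_cloud(0, 0, 5)))
  expect_equal(single$HMEAN, 5)
  expect_true(is.na(single$SDH))
})

test_that("fixed heights 1..10 reproduce hand-computed metrics", {
  m <- compute_metrics(prepare_als(point_cloud(rep(0, 10), rep(0, 10), 1:10)))
  expect_equal(m$HMEAN, 5.5)
  expect_equal(m$RHMEAN, 0.55)
  expect_equal(m$SDH, sd(1:10))
  expect_equal(m$PTN, 10)
  # H = 10: thirds at 10/3 and 20/3; bands {1,2,3}, {4,5,6}, {7..10}
  expect_equal(m$PP_1_3, 0.3)
  expect_equal(m$PP_2_3, 0.3)
  expect_equal(m$PP_3_3, 0.4)
  expect_equal(m$HM_1_3, 2)
  expect_equal(m$HM_2_3, 5)
  expect_equal(m$HM_3_3, 8.5)
  # a 22 m cloud puts the thirds boundaries at 22/3 and 44/3
  m22 <- compute_metrics(prepare_als(point_cloud(rep(0, 4), rep(0, 4),
                                                 c(2, 8, 15, 22))))
  expect_equal(m22$PP_1_3, 0.25)  # only z = 2 below 7.33
  expect_equal(m22$PP_2_3, 0.25)  # z = 8 in [7.33, 14.67)
  expect_equal(m22$PP_3_3, 0.5)   # 15 and 22
})

test_that("all 17 metrics match the direct-formula oracle", {
  skip_if_not_installed("e1071")
  for (s in 1:5) {
    set.seed(40 + s)
    n <- sample(50:500, 1)
    cloud <- point_cloud(runif(n), runif(n), rlnorm(n, log(6), 0.7),
                         classification = sample(c(1L, 2L), n, TRUE,
                                                 prob = c(0.8, 0.2)))
    prep <- prepare_als(cloud)
    m <- compute_metrics(prep, unit_id = "x")
    orc <- oracle_metrics(prep$z, ogp = attr(prep, "ogp"))
    for (nm in als_metric_names())
      expect_equal(m[[nm]], orc[[nm]], tolerance = 1e-12, label = nm)
    expect_equal(m$PP_1_3 + m$PP_2_3 + m$PP_3_3, 1)
  }
})

test_that("metrics respect permutation, translation and scaling laws", {
  set.seed(51)
  z <- rlnorm(300, log(5), 0.6)
  z <- z[z >= 0.5 & z <= 22]
  base <- compute_metrics(prepare_als(point_cloud(runif(length(z)),
                                                  runif(length(z)), z)))
  perm <- sample(seq_along(z))
  shuf <- compute_metrics(prepare_als(point_cloud(runif(length(z)),
                                                  runif(length(z)),
                                                  z[perm])))
  for (nm in als_metric_names())
    expect_equal(shuf[[nm]], base[[nm]], label = nm)
  # scaling z by c scales the height metrics and fixes the shape metrics
  c0 <- 0.5  # keeps everything inside the cap
  scaled <- compute_metrics(prepare_als(point_cloud(runif(length(z)),
                                                    runif(length(z)),
                                                    z * c0), floor = 0.25))
  for (nm in c("RHMEAN", "HCV", "HS", "HK", "PP_1_3", "PP_2_3", "PP_3_3"))
    expect_equal(scaled[[nm]], base[[nm]], tolerance = 1e-12, label = nm)
  for (nm in c("HMEAN", "SDH", "HM_1_3", "HM_2_3", "HM_3_3"))
    expect_equal(scaled[[nm]], c0 * base[[nm]], tolerance = 1e-12,
                 label = nm)
})
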
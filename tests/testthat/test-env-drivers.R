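test_that("Mantel statistic hits its limits and matches vegan's", {
  set.seed(14)
  pts <- matrix(rnorm(24), 12, 2)
  rownames(pts) <- paste0("s", 1:12)
  d <- dist(pts)
  res <- mantel(d, d, n_perm = 199, seed = 3)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)

  d2 <- dist(matrix(rnorm(24), 12, 2, dimnames = list(rownames(pts), NULL)))
  ours <- mantel(d, d2, n_perm = 199, seed = 1)
  ref <- vegan::mantel(d, d2, permutations = 199)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)

  # symmetry of the statistic in its two arguments
  swapped <- mantel(d2, d, n_perm = 199, seed = 1)
  expect_equal(ours$r, swapped$r, tolerance = 1e-12)

  d3 <- dist(matrix(rnorm(10), 5, 2,
                    dimnames = list(paste0("x", 1:5), NULL)))
  expect_error(mantel(d, d3), "differ")
})

test_that("haversine distances reproduce analytic arcs and metric axioms", {
  md <- data.frame(sample = c("p1", "p2", "p3"),
                   latitude = c(0, 0, 28.5), longitude = c(0, 180, 89))
  d <- geo_distance(md)
  dm <- as.matrix(d)
  expect_equal(dm["p1", "p2"], pi * 6371, tolerance = 1e-3)

  md2 <- data.frame(sample = c("a", "b"), latitude = c(28.5, 29.5),
                    longitude = c(89, 89))
  one_deg <- as.matrix(geo_distance(md2))["a", "b"]
  expect_equal(one_deg, pi * 6371 / 180, tolerance = 1e-3)
  expect_equal(as.matrix(geo_distance(md2[c(1, 1), ]))[1, 2], 0)

  set.seed(6)
  for (i in 1:10) {
    tri <- data.frame(sample = c("a", "b", "c"),
                      latitude = runif(3, -60, 60),
                      longitude = runif(3, -180, 180))
    dm <- as.matrix(geo_distance(tri))
    expect_equal(dm, t(dm))
    expect_lte(dm["a", "c"], dm["a", "b"] + dm["b", "c"] + 1e-9)
  }

  md$latitude[2] <- NA
  expect_error(geo_distance(md), "p2")
})

test_that("distance-decay recovers an exactly linear relationship", {
  md <- data.frame(sample = paste0("s", 1:8),
                   latitude = seq(28, 29.4, length.out = 8), longitude = 89)
  dg <- geo_distance(md)
  d_comm <- 0.2 + 0.003 * dg   # exact linear response
  attr(d_comm, "Labels") <- attr(dg, "Labels")
  fit <- distance_decay(d_comm, dg, n_perm = 199, seed = 2)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 0.003, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-9)
  expect_equal(fit$p, 1 / 200)

  const <- stats::as.dist(matrix(2, 8, 8) - 2 * diag(8))
  attr(const, "Labels") <- md$sample
  expect_warning(fit0 <- distance_decay(d_comm, const), "constant predictor")
  expect_true(is.na(fit0$slope) && fit0$degenerate)
})

test_that("decay permutation p is null-calibrated on shuffled responses", {
  set.seed(9)
  md <- data.frame(sample = paste0("s", 1:12),
                   latitude = runif(12, 28, 29.4),
                   longitude = runif(12, 88.9, 89.6))
  dg <- geo_distance(md)
  hits <- vapply(1:20, function(i) {
    y <- dist(rnorm(12))
    attr(y, "Labels") <- md$sample
    distance_decay(y, dg, n_perm = 99, seed = i)$p > 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("strong SWC filtering is detected by the Mantel panel, pH is not", {
  hits <- vapply(1:10, function(i) {
    sim <- simulate_filtered(small_filtered_scn(8, seed = 300 + i))
    d <- bray_curtis(sim$abundance)
    mt <- mantel_env(d, sim$env, c("SWC", "pH"), n_perm = 99, seed = i)
    c(swc_sig = mt$p[mt$factor == "SWC"] < 0.05,
      swc_stronger = mt$r[mt$factor == "SWC"] > mt$r[mt$factor == "pH"])
  }, c(swc_sig = TRUE, swc_stronger = TRUE))
  expect_gte(mean(hits["swc_sig", ]), 0.9)
  expect_gte(mean(hits["swc_stronger", ]), 0.9)
})

test_that("SWC decay fit outranks the unlinked pH fit on filtered communities", {
  sim <- simulate_filtered(small_filtered_scn(8, seed = 77))
  d <- bray_curtis(sim$abundance)
  de_swc <- env_distance(sim$env, "SWC")
  de_ph <- env_distance(sim$env, "pH")
  f_swc <- distance_decay(d, de_swc, n_perm = 99, seed = 1)
  f_ph <- distance_decay(d, de_ph, n_perm = 99, seed = 1)
  expect_gt(abs(f_swc$r), abs(f_ph$r))
})
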
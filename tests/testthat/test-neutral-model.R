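test_that("the fitted m covers the generating value and ubiquitous species fit tightly", {
  scn <- sim_scenario(n_species = 150,
                      habitats = c(A = 5, B = 5, C = 5, D = 5),
                      seasons = c("sp", "su", "au"),
                      migration_m = 0.1, community_size_N = 1000, seed = 42)
  fit <- fit_ncm(simulate_neutral(scn))
  expect_true(all(is.finite(fit$m_ci)))
  expect_gte(0.1, fit$m_ci[1])
  expect_lte(0.1, fit$m_ci[2])
  expect_gt(fit$R2, 0.9)
  expect_equal(fit$Nm, fit$N * fit$m)

  ubiquitous <- fit$data[fit$data$freq == 1 & fit$data$p > 0.02, ]
  if (nrow(ubiquitous)) {
    expect_true(all(ubiquitous$pred > 0.99))
    expect_true(all(abs(ubiquitous$freq - ubiquitous$pred) < 0.01))
  }
})

test_that("predicted occurrence frequency is monotone in abundance for both detection models", {
  scn <- sim_scenario(n_species = 60, community_size_N = 400, seed = 9)
  ab <- simulate_neutral(scn)
  p_grid <- 10^seq(-5, -0.5, length.out = 100)
  for (det in c("betabinomial", "threshold")) {
    fit <- fit_ncm(ab, detection = det)
    pred <- predict(fit, p = p_grid)
    expect_true(all(diff(pred) >= -1e-12))
    expect_true(all(pred >= 0 & pred <= 1))
  }
})

test_that("envelope partition fractions form a complete partition", {
  scn <- sim_scenario(n_species = 80, community_size_N = 300, seed = 4)
  fit <- fit_ncm(simulate_neutral(scn))
  expect_equal(fit$fraction_within + fit$fraction_below + fit$fraction_above,
               1, tolerance = 1e-12)
  expect_true(all(fit$data$lower >= 0 & fit$data$upper <= 1))
  expect_true(all(fit$data$lower <= fit$data$upper))
  expect_equal(1 - fit$R2,
               sum((fit$data$freq - fit$data$pred)^2) /
                 sum((fit$data$freq - mean(fit$data$freq))^2),
               tolerance = 1e-12)
})

test_that("optimizer solution matches a brute-force grid search", {
  scn <- sim_scenario(n_species = 20, habitats = c(A = 3, B = 3),
                      seasons = "su", community_size_N = 150, seed = 31)
  ab <- simulate_neutral(scn)
  fit <- fit_ncm(ab)
  grid <- seq(0.001, 1, by = 0.001)
  m0 <- ab$counts
  p <- colMeans(m0 / rowSums(m0))
  freq <- colMeans(m0 > 0)
  keep <- p > 0
  p <- p[keep]; freq <- freq[keep]
  N <- mean(rowSums(m0))
  sse <- vapply(grid, function(m) {
    a <- N * m * p; b <- N * m * (1 - p)
    pred <- 1 - exp(lbeta(a, b + N) - lbeta(a, b))
    sum((freq - pred)^2)
  }, 0)
  expect_lt(abs(fit$m - grid[which.min(sse)]), 0.0011)
})

test_that("R-squared is reported unclamped, including negative values", {
  # abundant-but-rarely-occurring vs rare-but-ubiquitous species defeat
  # the neutral curve, forcing SS_res > SS_tot
  m <- rbind(
    s1 = c(960, rep(1, 8), 0), s2 = c(0, rep(1, 8), 500),
    s3 = c(970, rep(1, 8), 0), s4 = c(0, rep(1, 8), 600),
    s5 = c(950, rep(1, 8), 0), s6 = c(0, rep(1, 8), 700))
  colnames(m) <- paste0("sp", 1:10)
  fit <- fit_ncm(abundance_table(m))
  expect_true(is.finite(fit$R2))
  expect_lt(fit$R2, 0)
})

test_that("degenerate all-present communities flag an undefined R-squared", {
  m <- matrix(5 + rpois(60, 3), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("sp", 1:10)))
  expect_warning(fit <- fit_ncm(abundance_table(m)), "R\\^2 undefined")
  expect_true(is.na(fit$R2))
  expect_true(fit$degenerate)
})

test_that("fit preconditions are enforced", {
  small <- matrix(1:8 + 1, 4, 2,
                  dimnames = list(paste0("s", 1:4), c("a", "b")))
  expect_error(fit_ncm(abundance_table(small)), "5 samples")
  thin <- matrix(rpois(30, 4) + 1, 6, 5,
                 dimnames = list(paste0("s", 1:6), paste0("sp", 1:5)))
  expect_error(fit_ncm(abundance_table(thin)), "10 species")
})

test_that("scope comparison ranks by fit quality with stable ties", {
  scn <- sim_scenario(n_species = 60, community_size_N = 400,
                      habitats = c(A = 6, B = 6), seasons = c("sp", "su"),
                      seed = 15)
  ab <- simulate_neutral(scn)
  f1 <- fit_ncm(ab, scope = list(ecosystem = "A"))
  f2 <- fit_ncm(ab, scope = list(ecosystem = "B"))
  cmp <- compare_scopes(list(A = f1, B = f2, A2 = f1))
  expect_equal(cmp$R2, sort(cmp$R2, decreasing = TRUE))
  # stable tie: A precedes its duplicate A2
  expect_lt(which(cmp$scope == "A"), which(cmp$scope == "A2"))
  expect_error(compare_scopes(list(f1)), "at least 2")

  # neutral data must outrank strongly filtered data of the same size
  simf <- simulate_filtered(small_filtered_scn(10, seed = 61,
                                               n_species = 60,
                                               community_size_N = 400))
  fn <- fit_ncm(simulate_neutral(small_filtered_scn(0, seed = 61,
                                                    n_species = 60,
                                                    community_size_N = 400)))
  ff <- fit_ncm(simf$abundance)
  cmp2 <- compare_scopes(list(neutral = fn, filtered = ff))
  expect_equal(cmp2$scope[1], "neutral")
})
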
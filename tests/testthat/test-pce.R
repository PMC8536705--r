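design <- build_design(default_parameter_set())

test_that("spectral projection recovers known expansions exactly", {
  # constant output: only the mean term survives
  pce <- fit_pce(design, rep(9.5, 125))
  expect_equal(pce$coeffs[1, 1], 9.5)
  expect_lt(max(abs(pce$coeffs[-1, 1])), 1e-10)

  # pure linear term in w
  pce <- fit_pce(design, design$nodes_std[, "w"])
  k_lin <- which(apply(pce$basis, 1, function(a) all(a == c(1, 0, 0))))
  expect_equal(pce$coeffs[k_lin, 1], 1, tolerance = 1e-12)
  expect_lt(max(abs(pce$coeffs[-c(1, k_lin), 1])), 1e-10)
  expect_lt(abs(pce$coeffs[1, 1]), 1e-12)

  # Y = xi_w^2 * xi_kappa: c_(2,1,0) = sqrt(2), c_(0,1,0) = 1
  y <- design$nodes_std[, "w"]^2 * design$nodes_std[, "kappa"]
  pce <- fit_pce(design, y)
  k210 <- which(apply(pce$basis, 1, function(a) all(a == c(2, 1, 0))))
  k010 <- which(apply(pce$basis, 1, function(a) all(a == c(0, 1, 0))))
  expect_equal(pce$coeffs[k210, 1], sqrt(2), tolerance = 1e-12)
  expect_equal(pce$coeffs[k010, 1], 1, tolerance = 1e-12)
  expect_lt(max(abs(pce$coeffs[-c(k210, k010), 1])), 1e-10)
})

test_that("projection agrees with a Monte-Carlo projection oracle", {
  f <- function(xi) xi[, 1]^2 * xi[, 2]
  for (alpha in list(c(2, 1, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 1))) {
    mc <- mc_projection(f, alpha, n = 1e6, seed = 42)
    pce <- fit_pce(design, f(design$nodes_std))
    k <- which(apply(pce$basis, 1, function(a) all(a == alpha)))
    expect_lt(abs(pce$coeffs[k, 1] - mc$estimate), 4 * mc$se)
  }
})

test_that("any cubic output is reconstructed exactly at the design nodes", {
  for (seed in 1:5) {
    f <- random_cubic(seed)
    y <- f(design$nodes_std)
    pce <- fit_pce(design, y)
    yhat <- pce_eval(pce, design$nodes_std)[, 1]
    expect_equal(yhat, y, tolerance = 1e-9)
  }
})

test_that("shape and validity errors are raised", {
  expect_error(fit_pce(design, rep(1, 124)), "124 rows")
  expect_error(fit_pce(design, c(rep(1, 124), NA)), "missing")
  expect_error(ensemble_moments(design, rep(1, 7)), "rows")
})

test_that("analytic Sobol fractions come out of the decomposition", {
  xs <- design$nodes_std
  # additive: variances 9 and 16
  sob <- sobol_decompose(fit_pce(design, 3 * xs[, "w"] + 4 * xs[, "a"]))
  expect_equal(unname(sob$fractions["S_w", 1]), 36, tolerance = 1e-10)
  expect_equal(unname(sob$fractions["S_a", 1]), 64, tolerance = 1e-10)
  others <- setdiff(rownames(sob$fractions), c("S_w", "S_a"))
  expect_lt(max(sob$fractions[others, 1]), 1e-8)

  # pure pairwise interaction
  sob <- sobol_decompose(fit_pce(design, xs[, "w"] * xs[, "kappa"]))
  expect_equal(unname(sob$fractions["S_w_kappa", 1]), 100, tolerance = 1e-10)
  expect_lt(max(sob$fractions[c("S_w", "S_kappa", "S_a"), 1]), 1e-8)

  # He1 and He3 both belong to the singleton group {w}
  sob <- sobol_decompose(fit_pce(design, xs[, "w"] + xs[, "w"]^3))
  expect_equal(unname(sob$fractions["S_w", 1]), 100, tolerance = 1e-10)
})

test_that("zero-variance gridpoints get missing fractions, never zeros", {
  y <- cbind(rep(5, 125), design$nodes_std[, "a"])
  sob <- sobol_decompose(fit_pce(design, y))
  expect_true(all(is.na(sob$fractions[, 1])))
  expect_equal(sob$total_variance[[1]], 0)
  expect_equal(sob$fractions[["S_a", 2]], 100, tolerance = 1e-10)
})

test_that("Sobol fractions are complete and within [0, 100] on random cubics", {
  y <- sapply(1:10, function(s) random_cubic(s)(design$nodes_std))
  sob <- sobol_decompose(fit_pce(design, y))
  expect_true(all(sob$fractions >= 0 & sob$fractions <= 100))
  expect_equal(unname(colSums(sob$fractions)), rep(100, 10),
               tolerance = 1e-6)
})

test_that("PCE Sobol indices match the Saltelli Monte-Carlo oracle", {
  # spot check here at moderate n; the full 20-function sweep at n = 1e5
  # runs in the acceptance suite
  for (seed in 1:3) {
    f <- random_cubic(seed)
    sob <- sobol_decompose(fit_pce(design, f(design$nodes_std)))
    mc <- saltelli_sobol(f, n = 2e4, seed = 100 + seed)
    expect_lt(max(abs(sob$fractions[1:3, 1] / 100 - mc$main) / mc$main_se),
              3)
    expect_lt(max(abs(sob$fractions[4:6, 1] / 100 - mc$pair) / mc$pair_se),
              3)
  }
})

test_that("weighted moments match PCE variance and exact normal moments", {
  xs <- design$nodes_std
  mom <- ensemble_moments(design, rep(9.5, 125))
  expect_equal(mom$mean, 9.5)
  expect_equal(mom$sd, 0)

  mom <- ensemble_moments(design, xs[, "w"])
  expect_equal(mom$mean, 0, tolerance = 1e-10)
  expect_equal(mom$sd, 1, tolerance = 1e-10)

  f <- random_cubic(11)
  y <- f(xs)
  pce <- fit_pce(design, y)
  mom <- ensemble_moments(design, y)
  expect_equal(mom$sd^2, sum(pce$coeffs[-1, 1]^2), tolerance = 1e-9)
  expect_equal(mom$mean, pce$coeffs[1, 1], tolerance = 1e-12)

  # unweighted moments are the plain ensemble statistics
  mom_u <- ensemble_moments(design, y, unweighted = TRUE)
  expect_equal(mom_u$mean, mean(y))
  expect_equal(mom_u$sd, sqrt(mean((y - mean(y))^2)))
})

test_that("truncation floors barely perturb Sobol indices of smooth outputs", {
  ps_floor <- default_parameter_set(floor_frac = 0.05)
  ps_nofloor <- default_parameter_set(floor_frac = 0)
  d1 <- build_design(ps_floor)
  d0 <- build_design(ps_nofloor)
  # smooth function of the physical parameters
  f_phys <- function(np) np[, "w"] / 15 + 2 * np[, "kappa"] / 3e-5 +
    (np[, "a"] / 0.6)^2
  s1 <- sobol_decompose(fit_pce(d1, f_phys(d1$nodes_phys)))
  s0 <- sobol_decompose(fit_pce(d0, f_phys(d0$nodes_phys)))
  expect_lt(max(abs(s1$fractions - s0$fractions)), 1)  # percentage points
})
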
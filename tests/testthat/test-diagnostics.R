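fx <- small_fixture(n_columns = 20, seed = 9, points_per_dim = 3)
arc <- fx$archive
design <- fx$design

test_that("change fields difference slices run-by-run", {
  expect_equal(change_field(arc, 2000, 2000),
               matrix(0, nrow = dim(arc$min_o2)[1],
                      ncol = dim(arc$min_o2)[2]))
  ch <- change_field(arc, 1850, 2100)
  expect_equal(ch, -change_field(arc, 2100, 1850))
  expect_equal(ch[3, 5],
               unname(arc$min_o2[3, 5, "2100"] - arc$min_o2[3, 5, "1850"]))
  expect_error(change_field(arc, 1850, 1990), "not present")
})

test_that("noise-to-signal ratio is guarded and in percent", {
  w <- c(0.5, 0.5)
  expect_equal(noise_to_signal(matrix(c(-20, -20), ncol = 1), w), 0)
  expect_equal(noise_to_signal(matrix(c(-15, -5), ncol = 1), w), 50)
  expect_true(is.na(noise_to_signal(matrix(c(-1, 1), ncol = 1), w)))
})

test_that("contemporary CV equals the noise-to-signal of the raw 2000 field", {
  maps <- contemporary_spread_maps(arc)
  ns <- noise_to_signal(arc$min_o2[, , "2000"], arc$weights)
  expect_equal(maps$cv, ns)
  expect_true(all(maps$spread >= 0))
  # identical members at a gridpoint give zero spread and zero CV
  arc0 <- arc
  arc0$min_o2[, 1, "2000"] <- 7
  m0 <- contemporary_spread_maps(arc0)
  expect_equal(m0$spread[1], 0)
  expect_equal(m0$cv[1], 0)
})

test_that("low-variance mask triggers at the configured sd/mean threshold", {
  sob <- structure(list(
    total_variance = c((0.05 * 10)^2, (0.20 * 10)^2, 0),
    fractions = matrix(100 / 7, 7, 3,
                       dimnames = list(.sobol_terms, NULL)),
    output_name = "x"), class = "sobol_field")
  mask <- mask_low_variance(sob, mean_field = c(10, 10, 10),
                            threshold_frac = 0.06)
  expect_identical(mask, c(TRUE, FALSE, TRUE))
  expect_error(mask_low_variance(sob, 1:2), "match")
})

test_that("regional averages aggregate unmasked percentage indices", {
  sob <- sobol_decompose(fit_pce(design, arc$min_o2[, , "2000"]))
  regions <- regime_regions(arc)
  tab <- regional_average(sob, regions)
  expect_setequal(tab$region, unique(arc$columns$regime))

  # single-gridpoint region returns that gridpoint verbatim
  one <- regional_average(sob, region_set(solo = 4L))
  expect_equal(unlist(one[, .sobol_terms]),
               sob$fractions[, 4], ignore_attr = TRUE)

  # uniform indices across a region pass through unchanged
  sob_u <- sob
  sob_u$fractions[, ] <- sob$fractions[, 2]
  u <- regional_average(sob_u, regions)
  for (term in .sobol_terms)
    expect_equal(u[[term]], rep(sob$fractions[term, 2], nrow(u)),
                 ignore_attr = TRUE)

  # fully masked region yields a missing row with a logged notice
  expect_message(
    allmask <- regional_average(sob, region_set(gone = c(1L, 2L)),
                                mask = rep(TRUE, 20)),
    "no unmasked gridpoints")
  expect_true(all(is.na(allmask[, .sobol_terms])))
})

test_that("region sets must be named, non-empty and non-overlapping", {
  expect_error(region_set(list(1:3, 4:5)), "named")
  expect_error(region_set(a = integer(0)), "empty")
  expect_error(region_set(a = 1:3, b = 3:5), "overlap")
})

test_that("size-weighted regional averages recover the global mean", {
  sob <- sobol_decompose(fit_pce(design, arc$min_o2[, , "2000"]))
  regions <- regime_regions(arc)
  mask <- rep(FALSE, 20)
  tab <- regional_average(sob, regions, mask)
  global <- rowMeans(sob$fractions)
  pooled <- colSums(tab[, .sobol_terms] * tab$n_gridpoints) /
    sum(tab$n_gridpoints)
  expect_equal(unname(pooled), unname(global), tolerance = 1e-10)
})

test_that("benchmark scores respect spread eligibility and masking", {
  sob <- sobol_decompose(fit_pce(design, arc$min_o2[, , "2000"]))
  maps <- diagnostic_maps(arc, sob)
  bench <- benchmark_scores(sob, maps$contemporary_spread,
                            maps$low_variance_mask)
  eligible <- !maps$low_variance_mask &
    maps$contemporary_spread > bench$spread_threshold
  expect_equal(unname(bench$scores["kappa", eligible]),
               unname(sob$fractions["S_kappa", eligible]))
  expect_true(all(is.na(bench$scores[, !eligible])))
  expect_true(all(bench$top$score >= 0 & bench$top$score <= 100))
})

test_that("top kappa benchmarking columns sit where the Monte-Carlo oracle
           says kappa dominates", {
  # representative column per regime, brute-force Saltelli estimate of the
  # kappa main effect on the actual column solver
  ps <- default_parameter_set()
  grid <- column_grid()
  S_kappa_mc <- sapply(names(fx$cfg$regimes), function(rg) {
    forcing <- list(column_id = 1, regime = rg,
                    production = fx$cfg$regimes[[rg]]$production,
                    temp_offset = 0)
    f <- function(xi) {
      phys <- cbind(destandardize(ps$w, xi[, 1]),
                    destandardize(ps$kappa, xi[, 2]),
                    destandardize(ps$a, xi[, 3]))
      solve_columns_batch(phys, forcing, grid, 2, fx$cfg)$min_o2
    }
    saltelli_sobol(f, n = 4096, seed = 21)$main[2]
  })
  sob <- sobol_decompose(fit_pce(design, arc$min_o2[, , "2000"]))
  maps <- diagnostic_maps(arc, sob)
  bench <- benchmark_scores(sob, maps$contemporary_spread,
                            maps$low_variance_mask)
  top_kappa <- bench$top[bench$top$parameter == "kappa", ]
  top_regimes <- arc$columns$regime[top_kappa$gridpoint]
  # the oracle's kappa-dominant regime (among regimes with eligible
  # gridpoints) must host the top-ranked kappa benchmark columns
  eligible_regimes <- unique(arc$columns$regime[!is.na(bench$scores["kappa", ])])
  best <- names(which.max(S_kappa_mc[eligible_regimes]))
  expect_true(all(top_regimes == best))
})

test_that("contemporary and projected uncertainty are computed and
           imperfectly rank-correlated", {
  sob <- sobol_decompose(fit_pce(design, arc$min_o2[, , "2000"]))
  maps <- diagnostic_maps(arc, sob)
  rho <- uncertainty_rank_correlation(maps)
  expect_true(is.finite(rho))
  expect_lt(rho, 1)
})
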
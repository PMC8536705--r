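cfg <- toy_ocean_config()
grid <- column_grid()

test_that("saturation and export flux follow their closed forms", {
  expect_equal(o2_saturation(0), 350)
  expect_equal(o2_saturation(10), 290)
  Ts <- seq(-2, 35, by = 0.5)
  expect_true(all(diff(o2_saturation(Ts)) < 0))
  expect_error(o2_saturation(40), "within")

  expect_equal(export_flux(0, 1), 0)
  expect_equal(export_flux(0.3, 1, F_max = 40, K_a = 0.3), 20) # half-saturation
  a <- seq(0.01, 3, by = 0.01)
  F <- export_flux(a, 1)
  expect_true(all(diff(F) > 0))
  expect_true(all(diff(diff(F)) < 0))  # concave
})

test_that("remineralization profile integrates to the analytic column total", {
  rs <- remineralization_sink(F0 = 10, w = 15, r = 0.1, grid)
  expect_equal(rs$total, 10 * (1 - exp(-0.1 * 1000 / 15)))
  # pointwise J at cell centres approximates the exact cell integral
  expect_equal(sum(rs$J * grid$dz), rs$total, tolerance = 1e-3)
  # doubling w doubles the e-folding depth of the flux profile
  rs2 <- remineralization_sink(10, 30, 0.1, grid)
  expect_equal(rs$flux[grid$faces == 150] / 10,
               rs2$flux[grid$faces == 300] / 10, tolerance = 1e-12)
})

test_that("a zero-export column sits at saturation everywhere", {
  forcing <- list(column_id = 1, regime = "tropical", production = 0,
                  temp_offset = 0)
  sol <- solve_column(forcing, grid, w = 15, kappa = 3e-5, a = 0.6,
                      time_slice = 2000, config = cfg)
  sat <- o2_saturation(cfg$regimes$tropical$temperature[2])
  expect_equal(sol$O2, rep(sat, grid$n), tolerance = 1e-10)
  expect_equal(sol$min_o2, sat, tolerance = 1e-10)
  expect_false(sol$suboxic)
})

test_that("discrete surface influx balances total consumption", {
  for (rg in names(cfg$regimes)) {
    forcing <- list(column_id = 1, regime = rg,
                    production = cfg$regimes[[rg]]$production,
                    temp_offset = 0.1)
    for (slice in c(1850, 2000, 2100)) {
      sol <- solve_column(forcing, grid, 12, 2.5e-5, 0.7, slice, cfg)
      si <- match(slice, cfg$slices)
      reg <- cfg$regimes[[rg]]
      sat <- o2_saturation(reg$temperature[si] + 0.1)
      kap_surf <- 2.5e-5 * 86400 +
        reg$stratification[si] * reg$kappa_ml * 86400
      influx <- kap_surf * (sat - sol$O2_raw[1]) / (grid$dz / 2)
      F0 <- export_flux(0.7, reg$production) * reg$production_multiplier[si]
      total_J <- F0 * (1 - exp(-cfg$constants$r * grid$H / 12))
      expect_equal(influx, total_J, tolerance = 1e-8)
    }
  }
})

test_that("parameter directions move the oxygen minimum as expected", {
  for (rg in names(cfg$regimes)) {
    forcing <- list(column_id = 1, regime = rg,
                    production = cfg$regimes[[rg]]$production,
                    temp_offset = 0)
    base <- solve_column(forcing, grid, 15, 3e-5, 0.6, 2000, cfg)
    # doubling kappa never decreases the minimum
    more_mix <- solve_column(forcing, grid, 15, 6e-5, 0.6, 2000, cfg)
    expect_gte(more_mix$min_o2, base$min_o2)
    # raising the growth rate (more export) never raises the minimum
    more_growth <- solve_column(forcing, grid, 15, 3e-5, 0.9, 2000, cfg)
    expect_lte(more_growth$min_o2, base$min_o2)
    # w moves the minimum monotonically within each regime
    mins_w <- sapply(c(8, 12, 15, 20, 30), function(w)
      solve_column(forcing, grid, w, 3e-5, 0.6, 2000, cfg)$min_o2)
    expect_true(all(diff(mins_w) <= 1e-9) || all(diff(mins_w) >= -1e-9))
  }
})

test_that("halving the grid spacing changes the minimum by under 1%", {
  fine <- column_grid(1000, 5)
  for (rg in names(cfg$regimes)) {
    forcing <- list(column_id = 1, regime = rg,
                    production = cfg$regimes[[rg]]$production,
                    temp_offset = 0)
    m10 <- solve_column(forcing, grid, 15, 3e-5, 0.6, 2000, cfg)$min_o2
    m5 <- solve_column(forcing, fine, 15, 3e-5, 0.6, 2000, cfg)$min_o2
    expect_lt(abs(m5 - m10) / max(abs(m10), 1), 0.01)
  }
})

test_that("world generation is deterministic and honours regime fractions", {
  w1 <- generate_world(cfg, seed = 5)
  w2 <- generate_world(cfg, seed = 5)
  expect_identical(w1, w2)
  w3 <- generate_world(cfg, seed = 6)
  expect_false(identical(w1$columns$production, w3$columns$production))

  counts <- table(w1$columns$regime)
  expect_equal(counts[["deepwater"]], 20)
  expect_equal(counts[["tropical"]], 40)
  expect_equal(counts[["intermediate"]], 40)

  bad <- cfg
  bad$fractions <- c(deepwater = 0.5, tropical = 0.6, intermediate = 0.1)
  expect_error(generate_world(bad, 1), "fractions")
})

test_that("the ensemble archive is complete, ordered and bounded", {
  fx <- small_fixture(n_columns = 10, seed = 3, points_per_dim = 3)
  arc <- fx$archive
  expect_equal(dim(arc$min_o2), c(27, 10, 3))
  expect_false(anyNA(arc$min_o2))
  expect_identical(arc$nodes_phys, fx$design$nodes_phys)
  sat_max <- max(sapply(names(cfg$regimes), function(rg)
    o2_saturation(min(cfg$regimes[[rg]]$temperature) -
                    cfg$regimes[[rg]]$temp_jitter)))
  expect_true(all(arc$min_o2 >= 0))
  expect_true(all(arc$min_o2 <= sat_max))
  # rerun is bitwise identical
  arc2 <- run_ensemble(fx$design, generate_world(fx$cfg, 3), column_grid(),
                       fx$cfg)
  expect_identical(arc$min_o2, arc2$min_o2)
})

test_that("warming plus stratification loss deoxygenates every column", {
  fx <- small_fixture(n_columns = 15, seed = 11, points_per_dim = 3)
  change <- change_field(fx$archive, 1850, 2100)
  mom <- ensemble_moments(fx$design, change)
  expect_true(all(mom$mean <= 0))
  expect_true(all(change <= 1e-9))
})

test_that("ventilation-dominated columns vary less than tropical columns", {
  fx <- small_fixture(n_columns = 30, seed = 2, points_per_dim = 5)
  mom <- ensemble_moments(fx$design, fx$archive$min_o2[, , "2000"])
  cv <- 100 * mom$sd / mom$mean
  reg <- fx$archive$columns$regime
  expect_lt(mean(cv[reg == "deepwater"]), mean(cv[reg == "tropical"]))
})
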
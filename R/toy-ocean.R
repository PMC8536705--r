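#' Default configuration of the synthetic column ocean
#'
#' The synthetic world stands in for a full Earth-system model: many
#' independent water columns in three regime families, solved at three time
#' slices (preindustrial 1850, contemporary 2000, projected 2100). It is
#' deliberately not an emulator of any particular model — it reproduces the
#' causal pathways (production, sinking/remineralization, ventilation by
#' mixing, temperature-dependent solubility) and the regional contrast the
#' diagnostics must detect, nothing more.
#'
#' Regimes:
#' * `deepwater` — cold deep-water-formation columns: vigorous dynamic
#'   mixing over most of the column, low production, strong projected
#'   warming and stratification loss. Projected change is large but nearly
#'   insensitive to the three uncertain parameters.
#' * `tropical` — warm oxygen-minimum-zone columns: mixing confined to a
#'   thin surface layer, background diffusivity carries the ventilation at
#'   depth. Projected change is small but highly parameter-sensitive.
#' * `intermediate` — temperate columns between the two extremes.
#'
#' All constants carry documented units and may be overridden.
#'
#' @param n_columns Number of water columns (gridpoints).
#' @param fractions Named fractions of columns per regime; must sum to 1.
#' @return A list with blocks `grid`, `constants`, `regimes`, `n_columns`.
#' @export
toy_ocean_config <- function(n_columns = 100,
                             fractions = c(deepwater = 0.2, tropical = 0.4,
                                           intermediate = 0.4)) {
  if (abs(sum(fractions) - 1) > 1e-12 || any(fractions < 0))
    stop("regime fractions must be non-negative and sum to 1", call. = FALSE)
  list(
    n_columns = as.integer(n_columns),
    fractions = fractions,
    grid = list(H = 1000, dz = 10),          # m
    constants = list(
      S0 = 350,      # mmol m-3      : solubility at 0 degC
      S1 = 6,        # mmol m-3 K-1  : solubility decrease per degC
      F_max = 40,    # mmol O2-eq m-2 day-1 : maximal export flux
      K_a = 0.3,     # day-1         : half-saturation of export in growth
      r = 0.1        # day-1         : remineralization rate
    ),
    slices = c(1850L, 2000L, 2100L),
    regimes = list(
      deepwater = list(
        temperature = c(2.0, 2.6, 6.5),             # degC per slice
        production = 0.25, production_jitter = 0.10, # dimensionless L
        temp_jitter = 0.3,                           # degC
        z_ml = 800,                                  # m, mixed/convective layer
        kappa_ml = 1e-2, kappa_deep = 1e-3,          # m2 s-1, dynamic mixing
        stratification = c(1.0, 0.92, 0.55),
        production_multiplier = c(1.0, 1.0, 0.99)
      ),
      tropical = list(
        temperature = c(24.0, 24.4, 25.5),
        production = 0.10, production_jitter = 0.15,
        temp_jitter = 0.3,
        z_ml = 50,
        kappa_ml = 1e-3, kappa_deep = 0,
        stratification = c(1.0, 0.97, 0.85),
        production_multiplier = c(1.0, 0.99, 0.97)
      ),
      intermediate = list(
        temperature = c(12.0, 12.6, 15.0),
        production = 0.30, production_jitter = 0.12,
        temp_jitter = 0.3,
        z_ml = 150,
        kappa_ml = 5e-3, kappa_deep = 5e-5,
        stratification = c(1.0, 0.95, 0.75),
        production_multiplier = c(1.0, 0.995, 0.97)
      )
    )
  )
}

#' Uniform vertical grid of a water column
#'
#' @param H Total depth, m.
#' @param dz Cell thickness, m; `H` must be a multiple of `dz`.
#' @return List with cell-centre `depths`, face depths, `dz` and `H`.
#' @export
column_grid <- function(H = 1000, dz = 10) {
  if (dz <= 0 || H <= 0) stop("'H' and 'dz' must be positive", call. = FALSE)
  n <- round(H / dz)
  if (abs(n * dz - H) > 1e-9) stop("'H' must be a multiple of 'dz'",
                                   call. = FALSE)
  list(depths = (seq_len(n) - 0.5) * dz, faces = (0:n) * dz,
       dz = dz, H = H, n = as.integer(n))
}

#' Temperature-dependent surface oxygen saturation
#'
#' Linearized solubility `O2_sat = S0 - S1 * T`: warmer surface water holds
#' less dissolved oxygen, one of the two warming pathways to deoxygenation.
#'
#' @param temperature Surface temperature, degC, within `[-2, 35]`.
#' @param S0 Saturation at 0 degC, mmol m-3.
#' @param S1 Solubility decrease per degC, mmol m-3 K-1.
#' @return Saturation concentration, mmol O2 m-3.
#' @export
o2_saturation <- function(temperature, S0 = 350, S1 = 6) {
  if (any(temperature < -2 | temperature > 35))
    stop("'temperature' must lie within [-2, 35] degC", call. = FALSE)
  S0 - S1 * temperature
}

#' Export flux of organic matter out of the surface layer
#'
#' Production is controlled by the maximum phytoplankton growth rate `a`
#' through a saturating (Michaelis-Menten) response scaled by the column's
#' nutrient/light richness `L`: `F0 = F_max * L * a / (a + K_a)`.
#'
#' @param a Maximum growth rate, day-1, `>= 0`.
#' @param L Production factor, dimensionless, `>= 0`.
#' @param F_max Maximal areal export flux, mmol O2-equivalent m-2 day-1.
#' @param K_a Half-saturation growth rate, day-1.
#' @return Export flux `F0`, mmol O2-equivalent m-2 day-1.
#' @export
export_flux <- function(a, L, F_max = 40, K_a = 0.3) {
  if (any(a < 0) || any(L < 0)) stop("'a' and 'L' must be >= 0", call. = FALSE)
  F_max * L * a / (a + K_a)
}

#' Remineralization oxygen sink profile
#'
#' Detritus sinks at speed `w` and is remineralized at rate `r`, giving an
#' exponential flux profile `F(z) = F0 * exp(-r z / w)` and a volumetric
#' oxygen consumption `J(z) = (r / w) * F(z)` whose column integral is
#' `F0 * (1 - exp(-r H / w))`.
#'
#' @param F0 Export flux at the surface, mmol O2-eq m-2 day-1.
#' @param w Sinking speed, m day-1, `> 0`.
#' @param r Remineralization rate, day-1, `> 0`.
#' @param grid A [column_grid()].
#' @return List with `J` (consumption at cell centres, mmol m-3 day-1),
#'   `flux` (flux at cell faces) and `total` (exact column integral of J).
#' @export
remineralization_sink <- function(F0, w, r, grid) {
  if (w <= 0 || r <= 0) stop("'w' and 'r' must be positive", call. = FALSE)
  list(J = (r / w) * F0 * exp(-r * grid$depths / w),
       flux = F0 * exp(-r * grid$faces / w),
       total = F0 * (1 - exp(-r * grid$H / w)))
}

# Dynamic-mixing profile at given depths for one column: kappa_ml above
# the mixed/convective layer base, kappa_deep below (m2 s-1).
kappa_dyn_profile <- function(z, z_ml, kappa_ml, kappa_deep) {
  ifelse(z < z_ml, kappa_ml, kappa_deep)
}

SECONDS_PER_DAY <- 86400

# Steady-state diffusion-consumption solve for one column at one time
# slice, vectorized across an ensemble of parameter vectors.
#
# Solves d/dz[(kappa + s * kappa_dyn(z)) dO2/dz] = J(z) with a Dirichlet
# surface condition at saturation and zero flux through the bottom, by
# centred second-order finite volumes (Thomas algorithm, forward sweep over
# cells with vector arithmetic across runs). Consumption uses the exact
# cell integral of the exponential flux profile, so the discrete surface
# influx balances total consumption to machine precision.
#
# params: R x 3 matrix of physical (w [m day-1], kappa [m2 s-1], a [day-1]).
# Returns list(O2_raw = R x n matrix (unclipped), O2, min_o2, suboxic).
solve_columns_batch <- function(params, forcing, grid, slice_index, config) {
  cst <- config$constants
  reg <- config$regimes[[forcing$regime]]
  R <- nrow(params)
  n <- grid$n
  w <- params[, 1]
  kb <- params[, 2] * SECONDS_PER_DAY            # m2 day-1
  a <- params[, 3]

  s <- reg$stratification[slice_index]
  Tsurf <- reg$temperature[slice_index] + forcing$temp_offset
  pmult <- reg$production_multiplier[slice_index]
  sat <- o2_saturation(Tsurf, cst$S0, cst$S1)
  F0 <- export_flux(a, forcing$production, cst$F_max, cst$K_a) * pmult

  # cell-integrated consumption (n x R): difference of flux across faces
  E <- exp(-cst$r * outer(grid$faces, 1 / w))    # (n+1) x R
  JdZ <- (E[1:n, , drop = FALSE] - E[2:(n + 1), , drop = FALSE]) *
    rep(F0, each = n)

  kd <- kappa_dyn_profile(grid$depths, reg$z_ml, reg$kappa_ml,
                          reg$kappa_deep) * SECONDS_PER_DAY
  kcell <- outer(kb, s * kd, FUN = "+")          # R x n, at cell centres
  # conductances beta (R x n+1): harmonic mean of adjacent cell
  # diffusivities at interior faces (exact for a jump at a face);
  # beta_1 over the half cell at the surface
  beta <- matrix(0, R, n + 1)
  beta[, 1] <- kcell[, 1] / (grid$dz / 2)
  kl <- kcell[, 1:(n - 1), drop = FALSE]
  kr <- kcell[, 2:n, drop = FALSE]
  beta[, 2:n] <- (2 * kl * kr / (kl + kr)) / grid$dz

  # tridiagonal system, Thomas algorithm vectorized across runs
  O2 <- matrix(0, R, n)
  cp <- matrix(0, R, n)
  dp <- matrix(0, R, n)
  diag1 <- -(beta[, 1] + beta[, 2])
  cp[, 1] <- beta[, 2] / diag1
  dp[, 1] <- (t(JdZ)[, 1] - beta[, 1] * sat) / diag1
  tJ <- t(JdZ)
  for (i in 2:n) {
    di <- -(beta[, i] + beta[, i + 1])
    denom <- di - beta[, i] * cp[, i - 1]
    cp[, i] <- beta[, i + 1] / denom
    dp[, i] <- (tJ[, i] - beta[, i] * dp[, i - 1]) / denom
  }
  O2[, n] <- dp[, n]
  for (i in (n - 1):1) O2[, i] <- dp[, i] - cp[, i] * O2[, i + 1]

  suboxic <- apply(O2 < 0, 1, any)
  O2_clip <- pmax(O2, 0)
  list(O2_raw = O2, O2 = O2_clip,
       min_o2 = apply(O2_clip, 1, min), suboxic = suboxic,
       saturation = sat)
}

#' Solve one water column at one time slice
#'
#' Steady-state balance between downward diffusion of oxygen from a
#' saturated surface and remineralization consumption at depth, discretized
#' by centred second-order finite volumes on the uniform grid and solved as
#' a tridiagonal linear system (zero-flux bottom boundary). Negative
#' concentrations (possible because consumption is oxygen-independent) are
#' clipped to zero after solving and flagged as suboxic.
#'
#' @param forcing A single column forcing, as produced by
#'   [generate_world()] (one element of `world$forcings`).
#' @param grid A [column_grid()].
#' @param w Sinking speed, m day-1.
#' @param kappa Background diffusivity, m2 s-1.
#' @param a Maximum growth rate, day-1.
#' @param time_slice One of 1850, 2000, 2100.
#' @param config Toy-ocean configuration, see [toy_ocean_config()].
#' @return List with the clipped profile `O2` (mmol m-3 at cell centres),
#'   the unclipped `O2_raw`, the column minimum `min_o2`, the surface
#'   `saturation` and a `suboxic` flag recording whether clipping engaged.
#' @export
solve_column <- function(forcing, grid, w, kappa, a, time_slice,
                         config = toy_ocean_config()) {
  if (!all(is.finite(c(w, kappa, a))) || w <= 0 || kappa <= 0 || a <= 0)
    stop("'w', 'kappa', 'a' must be positive and finite", call. = FALSE)
  slice_index <- match(time_slice, config$slices)
  if (is.na(slice_index))
    stop(sprintf("unknown time slice %s", time_slice), call. = FALSE)
  res <- solve_columns_batch(matrix(c(w, kappa, a), nrow = 1),
                             forcing, grid, slice_index, config)
  list(O2 = res$O2[1, ], O2_raw = res$O2_raw[1, ], min_o2 = res$min_o2[1],
       saturation = res$saturation, suboxic = res$suboxic[1])
}

#' Generate the synthetic world of column forcings
#'
#' Deterministic given `seed`: assigns columns to regimes by the configured
#' fractions (largest-remainder rounding) and draws small per-column
#' perturbations of the production factor and surface temperature so that
#' columns within a regime are distinct.
#'
#' @param config See [toy_ocean_config()].
#' @param seed Integer seed; same seed and config give bitwise-identical
#'   forcings.
#' @return An object of class `column_world`: list with `columns` (a data
#'   frame of per-column regime labels and resolved forcing values) and
#'   `forcings` (per-column forcing lists used by the solver).
#' @export
generate_world <- function(config = toy_ocean_config(), seed = 1L) {
  fr <- config$fractions
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-12)
    stop("invalid regime fractions", call. = FALSE)
  if (!all(names(fr) %in% names(config$regimes)))
    stop("fractions name a regime missing from the config", call. = FALSE)
  N <- config$n_columns
  counts <- floor(fr * N)
  rem <- N - sum(counts)
  if (rem > 0) {
    extra <- order(fr * N - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  regime <- rep(names(fr), counts)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  production <- numeric(N)
  temp_offset <- numeric(N)
  for (rg in names(fr)) {
    idx <- which(regime == rg)
    rcfg <- config$regimes[[rg]]
    production[idx] <- rcfg$production *
      (1 + rcfg$production_jitter * runif(length(idx), -1, 1))
    temp_offset[idx] <- rcfg$temp_jitter * runif(length(idx), -1, 1)
  }
  columns <- data.frame(column_id = seq_len(N), regime = regime,
                        production = production, temp_offset = temp_offset,
                        stringsAsFactors = FALSE)
  forcings <- lapply(seq_len(N), function(i)
    list(column_id = i, regime = regime[i], production = production[i],
         temp_offset = temp_offset[i]))
  structure(list(columns = columns, forcings = forcings, seed = seed),
            class = "column_world")
}

#' Run the perturbed-parameter ensemble over the synthetic world
#'
#' Solves every column for every collocation design row and every time
#' slice, storing the water-column oxygen minimum. Run order matches the
#' design row order, which downstream spectral projection relies on.
#'
#' @param design A `quadrature_design` (see [build_design()]).
#' @param world A `column_world` (see [generate_world()]).
#' @param grid A [column_grid()]; defaults to the config grid.
#' @param config Toy-ocean configuration.
#' @return An object of class `ensemble_archive`: `min_o2` array of
#'   dimension run x column x time-slice (mmol O2 m-3), a matching
#'   `suboxic` flag array, the design metadata, slice years, regime labels
#'   and provenance (seed, config hash).
#' @export
run_ensemble <- function(design, world, grid = NULL,
                         config = toy_ocean_config()) {
  stopifnot(inherits(design, "quadrature_design"),
            inherits(world, "column_world"))
  if (is.null(grid)) grid <- column_grid(config$grid$H, config$grid$dz)
  R <- nrow(design$nodes_phys)
  N <- length(world$forcings)
  S <- length(config$slices)
  min_o2 <- array(NA_real_, dim = c(R, N, S),
                  dimnames = list(NULL, NULL, as.character(config$slices)))
  suboxic <- array(NA, dim = c(R, N, S))
  for (si in seq_len(S)) {
    for (ci in seq_len(N)) {
      res <- tryCatch(
        solve_columns_batch(design$nodes_phys, world$forcings[[ci]],
                            grid, si, config),
        error = function(e) stop(sprintf(
          "column %d, slice %s: %s", ci, config$slices[si],
          conditionMessage(e)), call. = FALSE))
      min_o2[, ci, si] <- res$min_o2
      suboxic[, ci, si] <- res$suboxic
    }
  }
  structure(
    list(min_o2 = min_o2, suboxic = suboxic,
         slices = config$slices, columns = world$columns,
         nodes_phys = design$nodes_phys, nodes_std = design$nodes_std,
         weights = design$weights, seed = world$seed,
         config_hash = config_digest(config)),
    class = "ensemble_archive"
  )
}

# Stable hash of a configuration list, for provenance attributes.
config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

#' @export
print.ensemble_archive <- function(x, ...) {
  d <- dim(x$min_o2)
  cat(sprintf(
    "Ensemble archive: %d runs x %d columns x %d time slices (%s)\n",
    d[1], d[2], d[3], paste(x$slices, collapse = ", ")))
  cat(sprintf("min O2 range: %.1f .. %.1f mmol m-3; %.1f%% suboxic entries\n",
              min(x$min_o2), max(x$min_o2), 100 * mean(x$suboxic)))
  invisible(x)
}
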
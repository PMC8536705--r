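O2_UNITS <- "mmol m-3"

# Known unit spellings convertible to mmol m-3 (multiplicative factors).
# Extendable per call through the 'conversions' argument of read_archive.
.default_unit_conversions <- c(
  "mmol m-3" = 1, "mmol/m3" = 1, "mmol/m^3" = 1,
  "mol m-3" = 1000, "mol/m3" = 1000,
  "umol l-1" = 1, "umol/l" = 1
)

#' Write an ensemble archive to NetCDF
#'
#' Dimensions `run` x `column` x `time_slice` with the water-column oxygen
#' minimum as the payload variable (units mmol m-3, CF-style attributes),
#' the collocation design (physical and standardized nodes, quadrature
#' weights) and per-column regime metadata, plus provenance attributes
#' (seed, configuration hash). No timestamp attributes are written, so
#' identical inputs produce byte-identical files.
#'
#' @param archive An `ensemble_archive`.
#' @param path Output file path (`.nc`).
#' @return `path`, invisibly.
#' @export
write_archive <- function(archive, path) {
  stopifnot(inherits(archive, "ensemble_archive"))
  d <- dim(archive$min_o2)
  dim_run <- ncdf4::ncdim_def("run", "", seq_len(d[1]),
                              create_dimvar = FALSE)
  dim_col <- ncdf4::ncdim_def("column", "", seq_len(d[2]),
                              create_dimvar = FALSE)
  dim_slice <- ncdf4::ncdim_def("time_slice", "year",
                                as.integer(archive$slices))
  dim_param <- ncdf4::ncdim_def("param", "", 1:3, create_dimvar = FALSE)

  v_min <- ncdf4::ncvar_def("min_O2", O2_UNITS,
                            list(dim_run, dim_col, dim_slice),
                            missval = NA_real_, prec = "double",
                            longname = "water-column minimum of dissolved O2")
  v_sub <- ncdf4::ncvar_def("suboxic", "1", list(dim_run, dim_col, dim_slice),
                            prec = "integer",
                            longname = "1 where the unclipped solution went negative")
  v_phys <- ncdf4::ncvar_def("nodes_phys", "", list(dim_run, dim_param),
                             prec = "double",
                             longname = "collocation nodes, physical units (w, kappa, a)")
  v_std <- ncdf4::ncvar_def("nodes_std", "1", list(dim_run, dim_param),
                            prec = "double",
                            longname = "collocation nodes, standardized")
  v_w <- ncdf4::ncvar_def("weights", "1", list(dim_run), prec = "double",
                          longname = "quadrature weights (sum to 1)")
  v_reg <- ncdf4::ncvar_def("regime", "1", list(dim_col), prec = "integer",
                            longname = "regime code per column")
  v_prod <- ncdf4::ncvar_def("production", "1", list(dim_col),
                             prec = "double")
  v_toff <- ncdf4::ncvar_def("temp_offset", "degC", list(dim_col),
                             prec = "double")

  nc <- ncdf4::nc_create(path, list(v_min, v_sub, v_phys, v_std, v_w,
                                    v_reg, v_prod, v_toff))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v_min, archive$min_o2)
  ncdf4::ncvar_put(nc, v_sub, archive$suboxic + 0L)
  ncdf4::ncvar_put(nc, v_phys, archive$nodes_phys)
  ncdf4::ncvar_put(nc, v_std, archive$nodes_std)
  ncdf4::ncvar_put(nc, v_w, archive$weights)
  regimes <- sort(unique(archive$columns$regime))
  ncdf4::ncvar_put(nc, v_reg, match(archive$columns$regime, regimes))
  ncdf4::ncvar_put(nc, v_prod, archive$columns$production)
  ncdf4::ncvar_put(nc, v_toff, archive$columns$temp_offset)
  ncdf4::ncatt_put(nc, v_reg, "levels", paste(regimes, collapse = ","))
  ncdf4::ncatt_put(nc, 0, "param_order", "w,kappa,a")
  ncdf4::ncatt_put(nc, 0, "seed", as.integer(archive$seed))
  ncdf4::ncatt_put(nc, 0, "config_hash", archive$config_hash)
  invisible(path)
}

#' Read a gridded ensemble archive from NetCDF
#'
#' Accepts archives written by [write_archive()] as well as externally
#' produced archives, provided they carry `run`, `column` (or a mapped
#' name) and `time_slice` dimensions and a run x column x slice variable of
#' water-column oxygen minima. Variable and dimension names can be remapped
#' through `var_map`; units other than mmol m-3 are converted through a
#' declared conversion table and anything unconvertible is an error.
#' Archives without design metadata get equal weights (with a message),
#' since weighted statistics are then the best available.
#'
#' @param path NetCDF file path.
#' @param var_map Named character vector remapping expected names to names
#'   in the file, e.g. `c(min_O2 = "o2min", column = "gridpoint")`.
#' @param conversions Named numeric vector of unit conversion factors to
#'   mmol m-3, merged over the built-in table.
#' @return An `ensemble_archive`.
#' @export
read_archive <- function(path, var_map = character(), conversions = NULL) {
  if (!file.exists(path)) stop(sprintf("archive file not found: %s", path),
                               call. = FALSE)
  nm <- function(x) if (x %in% names(var_map)) var_map[[x]] else x
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))

  dims <- names(nc$dim)
  for (d in c("run", "column", "time_slice")) {
    if (!nm(d) %in% dims)
      stop(sprintf("archive is missing required dimension '%s'", nm(d)),
           call. = FALSE)
  }
  if (!nm("min_O2") %in% names(nc$var))
    stop(sprintf("archive is missing required variable '%s'", nm("min_O2")),
         call. = FALSE)

  min_o2 <- ncdf4::ncvar_get(nc, nm("min_O2"), collapse_degen = FALSE)
  units <- ncdf4::ncatt_get(nc, nm("min_O2"), "units")
  conv <- .default_unit_conversions
  if (!is.null(conversions)) conv[names(conversions)] <- conversions
  if (units$hasatt) {
    u <- units$value
    if (!u %in% names(conv))
      stop(sprintf(
        "archive units '%s' are not convertible to %s; declare a conversion",
        u, O2_UNITS), call. = FALSE)
    min_o2 <- min_o2 * conv[[u]]
  }

  slice_dim <- nc$dim[[nm("time_slice")]]
  slices <- as.integer(slice_dim$vals)
  R <- dim(min_o2)[1]
  dimnames(min_o2) <- list(NULL, NULL, as.character(slices))

  getvar <- function(v) if (v %in% names(nc$var))
    ncdf4::ncvar_get(nc, v, collapse_degen = FALSE) else NULL
  weights <- getvar(nm("weights"))
  if (is.null(weights)) {
    message("archive carries no quadrature weights; assuming equal weights")
    weights <- rep(1 / R, R)
  }
  nodes_phys <- getvar(nm("nodes_phys"))
  nodes_std <- getvar(nm("nodes_std"))
  sub <- getvar(nm("suboxic"))
  suboxic <- if (is.null(sub)) array(NA, dim(min_o2)) else {
    s <- array(sub == 1L, dim(min_o2)); s
  }

  N <- dim(min_o2)[2]
  regime_codes <- getvar(nm("regime"))
  if (!is.null(regime_codes)) {
    lv <- ncdf4::ncatt_get(nc, nm("regime"), "levels")
    levels <- if (lv$hasatt) strsplit(lv$value, ",")[[1]] else
      as.character(sort(unique(regime_codes)))
    regime <- levels[regime_codes]
  } else {
    regime <- rep(NA_character_, N)
  }
  production <- getvar(nm("production"))
  temp_offset <- getvar(nm("temp_offset"))
  columns <- data.frame(
    column_id = seq_len(N), regime = regime,
    production = if (is.null(production)) NA_real_ else as.numeric(production),
    temp_offset = if (is.null(temp_offset)) NA_real_ else
      as.numeric(temp_offset),
    stringsAsFactors = FALSE)

  seed <- ncdf4::ncatt_get(nc, 0, "seed")
  hash <- ncdf4::ncatt_get(nc, 0, "config_hash")
  structure(
    list(min_o2 = min_o2, suboxic = suboxic, slices = slices,
         columns = columns, nodes_phys = nodes_phys, nodes_std = nodes_std,
         weights = as.numeric(weights),
         seed = if (seed$hasatt) seed$value else NA_integer_,
         config_hash = if (hash$hasatt) hash$value else NA_character_),
    class = "ensemble_archive"
  )
}

# String encoding of a multi-index basis, e.g. "0,0,0;1,0,0;...".
encode_basis <- function(basis) {
  paste(apply(basis, 1, paste, collapse = ","), collapse = ";")
}

decode_basis <- function(s) {
  rows <- strsplit(strsplit(s, ";")[[1]], ",")
  m <- do.call(rbind, lapply(rows, as.integer))
  dimnames(m) <- list(NULL, c("w", "kappa", "a"))
  m
}

#' Write a PCE coefficient field to NetCDF
#'
#' @param pce A `pce_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pce <- function(pce, path) {
  stopifnot(inherits(pce, "pce_field"))
  dim_basis <- ncdf4::ncdim_def("basis", "", seq_len(nrow(pce$basis)),
                                create_dimvar = FALSE)
  dim_col <- ncdf4::ncdim_def("column", "", seq_len(ncol(pce$coeffs)),
                              create_dimvar = FALSE)
  v_c <- ncdf4::ncvar_def("coeffs", "", list(dim_basis, dim_col),
                          prec = "double",
                          longname = "PCE coefficients (orthonormal Hermite basis)")
  nc <- ncdf4::nc_create(path, list(v_c))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v_c, pce$coeffs)
  ncdf4::ncatt_put(nc, v_c, "multi_indices", encode_basis(pce$basis))
  ncdf4::ncatt_put(nc, 0, "output_name", pce$output_name)
  ncdf4::ncatt_put(nc, 0, "max_order", as.integer(pce$max_order))
  invisible(path)
}

#' Read a PCE coefficient field from NetCDF
#'
#' @param path File written by [write_pce()].
#' @return A `pce_field`.
#' @export
read_pce <- function(path) {
  if (!file.exists(path))
    stop(sprintf("PCE file not found: %s", path), call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  coeffs <- ncdf4::ncvar_get(nc, "coeffs", collapse_degen = FALSE)
  basis <- decode_basis(ncdf4::ncatt_get(nc, "coeffs", "multi_indices")$value)
  structure(
    list(basis = basis, coeffs = coeffs,
         max_order = ncdf4::ncatt_get(nc, 0, "max_order")$value,
         output_name = ncdf4::ncatt_get(nc, 0, "output_name")$value),
    class = "pce_field"
  )
}

#' Write a Sobol field to NetCDF
#'
#' Variables `S_w`, `S_kappa`, `S_a`, `S_w_kappa`, `S_w_a`, `S_kappa_a`,
#' `S_w_kappa_a` (percent) and `variance_total`; undefined fractions are
#' stored as the fill value.
#'
#' @param sobol A `sobol_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sobol <- function(sobol, path) {
  stopifnot(inherits(sobol, "sobol_field"))
  G <- length(sobol$total_variance)
  dim_col <- ncdf4::ncdim_def("column", "", seq_len(G),
                              create_dimvar = FALSE)
  fill <- -9999
  vars <- lapply(rownames(sobol$fractions), function(nm)
    ncdf4::ncvar_def(nm, "%", list(dim_col), missval = fill,
                     prec = "double"))
  v_tv <- ncdf4::ncvar_def("variance_total", "(mmol m-3)2", list(dim_col),
                           prec = "double")
  nc <- ncdf4::nc_create(path, c(vars, list(v_tv)))
  on.exit(ncdf4::nc_close(nc))
  for (i in seq_along(vars)) {
    x <- sobol$fractions[i, ]
    x[is.na(x)] <- fill
    ncdf4::ncvar_put(nc, vars[[i]], x)
  }
  ncdf4::ncvar_put(nc, v_tv, sobol$total_variance)
  ncdf4::ncatt_put(nc, 0, "output_name", sobol$output_name)
  invisible(path)
}

#' Read a Sobol field from NetCDF
#'
#' @param path File written by [write_sobol()].
#' @return A `sobol_field`.
#' @export
read_sobol <- function(path) {
  if (!file.exists(path))
    stop(sprintf("Sobol file not found: %s", path), call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  terms <- c("S_w", "S_kappa", "S_a", "S_w_kappa", "S_w_a", "S_kappa_a",
             "S_w_kappa_a")
  fr <- t(vapply(terms, function(v) {
    x <- as.numeric(ncdf4::ncvar_get(nc, v))
    x
  }, numeric(nc$dim$column$len)))
  structure(
    list(total_variance = as.numeric(ncdf4::ncvar_get(nc, "variance_total")),
         fractions = fr,
         output_name = ncdf4::ncatt_get(nc, 0, "output_name")$value),
    class = "sobol_field"
  )
}

#' Write diagnostic maps to NetCDF
#'
#' @param maps A `diagnostic_maps` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_maps <- function(maps, path) {
  stopifnot(inherits(maps, "diagnostic_maps"))
  G <- length(maps$mean_change)
  dim_col <- ncdf4::ncdim_def("column", "", seq_len(G),
                              create_dimvar = FALSE)
  fill <- -9999
  defs <- list(
    mean_change = O2_UNITS, noise_to_signal = "%",
    contemporary_mean = O2_UNITS, contemporary_spread = O2_UNITS,
    contemporary_cv = "%")
  vars <- lapply(names(defs), function(nm)
    ncdf4::ncvar_def(nm, defs[[nm]], list(dim_col), missval = fill,
                     prec = "double"))
  v_mask <- ncdf4::ncvar_def("low_variance_mask", "1", list(dim_col),
                             missval = -1L, prec = "integer")
  nc <- ncdf4::nc_create(path, c(vars, list(v_mask)))
  on.exit(ncdf4::nc_close(nc))
  for (i in seq_along(defs)) {
    x <- maps[[names(defs)[i]]]
    x[is.na(x)] <- fill
    ncdf4::ncvar_put(nc, vars[[i]], x)
  }
  m <- maps$low_variance_mask + 0L
  m[is.na(m)] <- -1L
  ncdf4::ncvar_put(nc, v_mask, m)
  invisible(path)
}

#' Read diagnostic maps from NetCDF
#'
#' @param path File written by [write_maps()].
#' @return A `diagnostic_maps` object.
#' @export
read_maps <- function(path) {
  if (!file.exists(path))
    stop(sprintf("maps file not found: %s", path), call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  out <- lapply(c("mean_change", "noise_to_signal", "contemporary_mean",
                  "contemporary_spread", "contemporary_cv"),
                function(v) as.numeric(ncdf4::ncvar_get(nc, v)))
  names(out) <- c("mean_change", "noise_to_signal", "contemporary_mean",
                  "contemporary_spread", "contemporary_cv")
  m <- as.integer(ncdf4::ncvar_get(nc, "low_variance_mask"))
  out$low_variance_mask <- ifelse(m < 0, NA, m == 1L)
  structure(out, class = "diagnostic_maps")
}

#' Default pipeline configuration
#'
#' One nested list collecting every tunable of the pipeline: the parameter
#' priors, the quadrature resolution, the synthetic-ocean settings, the
#' diagnostic thresholds and the region definitions. [read_config()] loads
#' the same structure from a YAML file and validates it.
#'
#' @param seed Seed for the synthetic world.
#' @return A named list with blocks `parameters`, `quadrature`, `ocean`,
#'   `diagnostics` and `regions`.
#' @export
default_config <- function(seed = 42L) {
  list(
    parameters = list(
      w     = list(mean = 15,   rel_sd = 0.5,  floor = 0.75),
      kappa = list(mean = 3e-5, rel_sd = 0.5,  floor = 1.5e-6),
      a     = list(mean = 0.6,  rel_sd = 0.25, floor = 0.03)
    ),
    quadrature = list(points_per_dim = 5L, max_order = 3L),
    ocean = c(toy_ocean_config(), list(seed = as.integer(seed))),
    diagnostics = list(eps = 1e-6, mask_threshold = 0.06,
                       spread_quantile = 0.5, unweighted = FALSE,
                       top_k = 5L),
    regions = list(by = "regime")
  )
}

.config_schema <- list(
  parameters = c("w", "kappa", "a"),
  quadrature = c("points_per_dim", "max_order"),
  ocean = c("n_columns", "fractions", "grid", "constants", "slices",
            "regimes", "seed"),
  diagnostics = c("eps", "mask_threshold", "spread_quantile", "unweighted",
                  "top_k"),
  regions = c("by", "boxes")
)

#' Validate a pipeline configuration
#'
#' Rejects unknown keys (with their location) and checks the parameter
#' block invariants. Returns the config invisibly on success.
#'
#' @param config A configuration list.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (blk in names(config)) {
    bad <- setdiff(names(config[[blk]]), .config_schema[[blk]])
    if (length(bad))
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (p in c("w", "kappa", "a")) {
    spec <- config$parameters[[p]]
    if (is.null(spec))
      stop(sprintf("parameters: block for '%s' is missing", p),
           call. = FALSE)
    bad <- setdiff(names(spec), c("mean", "rel_sd", "floor"))
    if (length(bad))
      stop(sprintf("unknown key(s) in parameters$%s: %s", p,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(config)
}

#' Read and validate a YAML pipeline configuration
#'
#' Any block omitted from the file keeps its default value; supplied keys
#' override defaults, and unknown keys are rejected with their location.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Parameter set from a configuration
#'
#' @param config A pipeline configuration list.
#' @return A `parameter_set`.
#' @export
config_parameter_set <- function(config) {
  p <- config$parameters
  parameter_set(
    w = uncertain_parameter("w", p$w$mean, p$w$rel_sd, p$w$floor),
    kappa = uncertain_parameter("kappa", p$kappa$mean, p$kappa$rel_sd,
                                p$kappa$floor),
    a = uncertain_parameter("a", p$a$mean, p$a$rel_sd, p$a$floor)
  )
}
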
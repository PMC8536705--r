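#' Run the full uncertainty-mapping pipeline
#'
#' Chains every stage in memory: collocation design, synthetic world and
#' ensemble, per-gridpoint PCE fits of the contemporary minimum and of the
#' projected change (2100 minus 1850), Sobol decompositions, diagnostic
#' maps, regional aggregation of the change-field sensitivities and the
#' benchmarking-region scores. With `out_dir` set, every product is also
#' written to NetCDF / TSV together with a JSON run manifest.
#'
#' @param config Pipeline configuration, see [default_config()] /
#'   [read_config()].
#' @param seed Overrides `config$ocean$seed` when given.
#' @param out_dir Optional output directory (created if needed).
#' @param unweighted Use equal ensemble weights in all diagnostics instead
#'   of the quadrature weights.
#' @param quiet Suppress progress/settings messages.
#' @return An object of class `oxyuq_report` collecting all intermediate
#'   and final products.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         out_dir = NULL, unweighted = FALSE, quiet = FALSE) {
  validate_config(config)
  if (!is.null(seed)) config$ocean$seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("settings: rel_sd = %s / %s / %s (w, kappa, a), points_per_dim = %d, max_order = %d, mask threshold = %g, seed = %d",
      config$parameters$w$rel_sd, config$parameters$kappa$rel_sd,
      config$parameters$a$rel_sd, config$quadrature$points_per_dim,
      config$quadrature$max_order, config$diagnostics$mask_threshold,
      config$ocean$seed)

  ps <- config_parameter_set(config)
  design <- build_design(ps, config$quadrature$points_per_dim)
  say("design: %d collocation runs", nrow(design$nodes_std))

  ocean <- config$ocean
  world <- generate_world(ocean, ocean$seed)
  grid <- column_grid(ocean$grid$H, ocean$grid$dz)
  archive <- run_ensemble(design, world, grid, ocean)
  say("ensemble: %d runs x %d columns x %d slices solved",
      dim(archive$min_o2)[1], dim(archive$min_o2)[2],
      dim(archive$min_o2)[3])

  products <- analyse_archive(archive, config, unweighted = unweighted,
                              quiet = quiet)
  out <- c(list(config = config, design = design, world = world,
                archive = archive), products)
  class(out) <- "oxyuq_report"
  if (!is.null(out_dir)) write_products(out, out_dir)
  out
}

#' Analyse an existing ensemble archive
#'
#' The analysis half of the pipeline, independent of the synthetic ocean:
#' works on any archive satisfying the schema (e.g. one read with
#' [read_archive()]).
#'
#' @param archive An `ensemble_archive`.
#' @param config Pipeline configuration (quadrature and diagnostics blocks
#'   are used).
#' @param unweighted Use equal ensemble weights.
#' @param quiet Suppress messages.
#' @return List of products: PCE and Sobol fields for the contemporary
#'   minimum and the projected change, diagnostic maps, masks, the
#'   regional Sobol table, benchmark scores and the contemporary/projected
#'   rank correlation.
#' @export
analyse_archive <- function(archive, config = default_config(),
                            unweighted = FALSE, quiet = FALSE) {
  stopifnot(inherits(archive, "ensemble_archive"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dg <- config$diagnostics
  design <- structure(
    list(nodes_std = archive$nodes_std, nodes_phys = archive$nodes_phys,
         weights = archive$weights,
         points_per_dim = as.integer(round(length(archive$weights)^(1 / 3)))),
    class = "quadrature_design")
  if (is.null(design$nodes_std))
    stop("archive carries no standardized nodes; PCE fitting needs them",
         call. = FALSE)

  contemporary <- archive$min_o2[, , "2000"]
  change <- change_field(archive, 1850, 2100)
  max_order <- config$quadrature$max_order

  pce_2000 <- fit_pce(design, contemporary, max_order, "min_O2_2000")
  pce_change <- fit_pce(design, change, max_order,
                        "delta_min_O2_1850_2100")
  sobol_2000 <- sobol_decompose(pce_2000)
  sobol_change <- sobol_decompose(pce_change)
  say("PCE/Sobol: %d basis terms, %d gridpoints", nrow(pce_2000$basis),
      ncol(pce_2000$coeffs))

  maps <- diagnostic_maps(archive, sobol_2000, unweighted = unweighted,
                          eps = dg$eps, threshold_frac = dg$mask_threshold)
  mom_change <- ensemble_moments(design, change, unweighted = unweighted)
  mask_change <- mask_low_variance(sobol_change, mom_change$mean,
                                   dg$mask_threshold)

  regions <- if (identical(config$regions$by, "regime") &&
                 !all(is.na(archive$columns$regime))) {
    regime_regions(archive)
  } else {
    region_set(all = seq_len(dim(archive$min_o2)[2]))
  }
  regional <- if (quiet) {
    suppressMessages(regional_average(sobol_change, regions, mask_change))
  } else {
    regional_average(sobol_change, regions, mask_change)
  }
  bench <- benchmark_scores(sobol_2000, maps$contemporary_spread,
                            maps$low_variance_mask,
                            spread_quantile = dg$spread_quantile,
                            top_k = dg$top_k)
  rho <- uncertainty_rank_correlation(maps)
  say("rank correlation (contemporary CV vs projected noise-to-signal): %.3f",
      rho)
  list(pce_2000 = pce_2000, pce_change = pce_change,
       sobol_2000 = sobol_2000, sobol_change = sobol_change,
       maps = maps, mask_change = mask_change, regions = regions,
       regional = regional, benchmark = bench, rank_correlation = rho,
       unweighted = unweighted)
}

# Write all pipeline products plus a manifest into out_dir.
write_products <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_archive(report$archive, p("archive.nc"))
  write_pce(report$pce_2000, p("pce_2000.nc"))
  write_pce(report$pce_change, p("pce_change.nc"))
  write_sobol(report$sobol_2000, p("sobol_2000.nc"))
  write_sobol(report$sobol_change, p("sobol_change.nc"))
  write_maps(report$maps, p("maps.nc"))
  write_regional_table(report$regional, p("regional_table.tsv"))
  utils::write.table(report$benchmark$top, p("benchmark_top.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c("archive.nc", "pce_2000.nc", "pce_change.nc", "sobol_2000.nc",
             "sobol_change.nc", "maps.nc", "regional_table.tsv",
             "benchmark_top.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("oxyuq")),
    seed = report$config$ocean$seed,
    config_hash = report$archive$config_hash,
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Write the regional Sobol table as delimited text
#'
#' Mirrors the layout of a regional sensitivity table: one row per region,
#' columns `region`, `S_w`, `S_kappa`, `S_a`, `S_w_kappa`, `S_w_a`,
#' `S_kappa_a`, `S_w_kappa_a`, all in percent.
#'
#' @param regional Data frame from [regional_average()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_regional_table <- function(regional, path) {
  cols <- c("region", "S_w", "S_kappa", "S_a", "S_w_kappa", "S_w_a",
            "S_kappa_a", "S_w_kappa_a")
  utils::write.table(format(regional[cols], digits = 4), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.oxyuq_report <- function(x, ...) {
  cat("Uncertainty-mapping pipeline report\n")
  cat("===================================\n")
  d <- dim(x$archive$min_o2)
  cat(sprintf("Ensemble: %d runs x %d columns x %d time slices\n",
              d[1], d[2], d[3]))
  cat(sprintf("Weighting: %s ensemble statistics\n\n",
              if (isTRUE(x$unweighted)) "unweighted" else
                "quadrature-weighted"))
  cat("Regional Sobol fractions of the projected change (%):\n")
  print(format(x$regional[, c("region", "n_gridpoints", "S_w", "S_kappa",
                              "S_a", "S_w_kappa", "S_w_a", "S_kappa_a",
                              "S_w_kappa_a")], digits = 3),
        row.names = FALSE)
  cat("\n")
  print(x$maps)
  cat(sprintf(
    "\nRank correlation, contemporary CV vs projected noise-to-signal: %.3f\n\n",
    x$rank_correlation))
  print(x$benchmark)
  invisible(x)
}

# --- file-based pipeline stages (the CLI surface) ------------------------

stage_path <- function(out_dir, f) file.path(out_dir, f)

require_stage_file <- function(path, producer) {
  if (!file.exists(path))
    stop(sprintf("missing dependency '%s'; run the '%s' stage first",
                 path, producer), call. = FALSE)
  path
}

#' File-based pipeline stages
#'
#' Each stage reads its inputs from and writes its products to `out_dir`,
#' so the pipeline can be driven step by step (e.g. from the shell
#' wrapper): `stage_design` writes the collocation design table,
#' `stage_simulate` the ensemble archive, `stage_fit` the PCE coefficient
#' fields, `stage_sobol` the Sobol fields, `stage_maps` the diagnostic
#' maps and `stage_report` the regional table and benchmark listing.
#' Missing upstream files raise an error naming the stage that produces
#' them.
#'
#' @param config Pipeline configuration.
#' @param out_dir Directory for stage products.
#' @param unweighted Use equal ensemble weights.
#' @return The path(s) written, invisibly (`stage_report` returns the
#'   report object).
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_design <- function(config = default_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- build_design(config_parameter_set(config),
                         config$quadrature$points_per_dim)
  tab <- data.frame(run = seq_len(nrow(design$nodes_std)),
                    design$nodes_std, design$nodes_phys,
                    weight = design$weights)
  names(tab) <- c("run", "xi_w", "xi_kappa", "xi_a", "w", "kappa", "a",
                  "weight")
  f <- stage_path(out_dir, "design.tsv")
  utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(f)
}

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config = default_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- build_design(config_parameter_set(config),
                         config$quadrature$points_per_dim)
  ocean <- config$ocean
  world <- generate_world(ocean, ocean$seed)
  archive <- run_ensemble(design, world,
                          column_grid(ocean$grid$H, ocean$grid$dz), ocean)
  f <- stage_path(out_dir, "archive.nc")
  write_archive(archive, f)
  invisible(f)
}

#' @rdname pipeline_stages
#' @export
stage_fit <- function(config = default_config(), out_dir) {
  archive <- read_archive(
    require_stage_file(stage_path(out_dir, "archive.nc"), "simulate"))
  design <- structure(
    list(nodes_std = archive$nodes_std, nodes_phys = archive$nodes_phys,
         weights = archive$weights, points_per_dim = NA_integer_),
    class = "quadrature_design")
  max_order <- config$quadrature$max_order
  f1 <- stage_path(out_dir, "pce_2000.nc")
  f2 <- stage_path(out_dir, "pce_change.nc")
  write_pce(fit_pce(design, archive$min_o2[, , "2000"], max_order,
                    "min_O2_2000"), f1)
  write_pce(fit_pce(design, change_field(archive, 1850, 2100), max_order,
                    "delta_min_O2_1850_2100"), f2)
  invisible(c(f1, f2))
}

#' @rdname pipeline_stages
#' @export
stage_sobol <- function(config = default_config(), out_dir) {
  f1 <- stage_path(out_dir, "sobol_2000.nc")
  f2 <- stage_path(out_dir, "sobol_change.nc")
  write_sobol(sobol_decompose(read_pce(
    require_stage_file(stage_path(out_dir, "pce_2000.nc"), "fit"))), f1)
  write_sobol(sobol_decompose(read_pce(
    require_stage_file(stage_path(out_dir, "pce_change.nc"), "fit"))), f2)
  invisible(c(f1, f2))
}

#' @rdname pipeline_stages
#' @export
stage_maps <- function(config = default_config(), out_dir,
                       unweighted = FALSE) {
  archive <- read_archive(
    require_stage_file(stage_path(out_dir, "archive.nc"), "simulate"))
  sobol_2000 <- read_sobol(
    require_stage_file(stage_path(out_dir, "sobol_2000.nc"), "sobol"))
  dg <- config$diagnostics
  maps <- diagnostic_maps(archive, sobol_2000, unweighted = unweighted,
                          eps = dg$eps, threshold_frac = dg$mask_threshold)
  f <- stage_path(out_dir, "maps.nc")
  write_maps(maps, f)
  invisible(f)
}

#' @rdname pipeline_stages
#' @export
stage_report <- function(config = default_config(), out_dir,
                         unweighted = FALSE) {
  archive <- read_archive(
    require_stage_file(stage_path(out_dir, "archive.nc"), "simulate"))
  products <- analyse_archive(archive, config, unweighted = unweighted,
                              quiet = TRUE)
  write_regional_table(products$regional,
                       stage_path(out_dir, "regional_table.tsv"))
  utils::write.table(products$benchmark$top,
                     stage_path(out_dir, "benchmark_top.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  out <- c(list(config = config, archive = archive), products)
  class(out) <- "oxyuq_report"
  out
}
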
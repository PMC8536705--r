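#' Per-run change field between two time slices
#'
#' @param archive An `ensemble_archive`.
#' @param from_slice,to_slice Slice years (e.g. 1850 and 2100); the change
#'   is `to - from` per run and gridpoint.
#' @return Run x gridpoint matrix of changes, mmol O2 m-3.
#' @export
change_field <- function(archive, from_slice = 1850, to_slice = 2100) {
  stopifnot(inherits(archive, "ensemble_archive"))
  f <- as.character(from_slice)
  t <- as.character(to_slice)
  for (s in c(f, t)) {
    if (!s %in% dimnames(archive$min_o2)[[3]])
      stop(sprintf("time slice %s not present in the archive", s),
           call. = FALSE)
  }
  archive$min_o2[, , t] - archive$min_o2[, , f]
}

# Internal: design weights of an archive, or equal weights.
archive_weights <- function(archive, unweighted = FALSE) {
  R <- dim(archive$min_o2)[1]
  if (unweighted) rep(1 / R, R) else archive$weights
}

# Weighted mean/sd over rows of a run x gridpoint matrix.
weighted_row_moments <- function(x, w) {
  m <- colSums(x * w)
  v <- colSums((x - rep(m, each = nrow(x)))^2 * w)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

#' Noise-to-signal map of an ensemble change field
#'
#' The ensemble standard deviation of the change normalized by the local
#' amplitude of the ensemble mean change, in percent: a measure of how much
#' parametric uncertainty obscures the projected signal. Where the mean
#' amplitude falls below `eps` the ratio is reported as `NA` (an explicit
#' missing sentinel, never infinity or zero).
#'
#' @param change Run x gridpoint change matrix (see [change_field()]).
#' @param weights Quadrature weights, one per run (equal weights give the
#'   naive ensemble statistic).
#' @param eps Mean-amplitude guard, mmol m-3.
#' @return Percent noise-to-signal per gridpoint, `NA` where undefined.
#' @export
noise_to_signal <- function(change, weights, eps = 1e-6) {
  if (is.null(dim(change))) change <- matrix(change, ncol = 1)
  mom <- weighted_row_moments(change, weights)
  out <- rep(NA_real_, length(mom$mean))
  ok <- abs(mom$mean) > eps
  out[ok] <- 100 * mom$sd[ok] / abs(mom$mean[ok])
  out
}

#' Contemporary ensemble spread and coefficient of variation
#'
#' Spread is the (weighted) ensemble standard deviation of the contemporary
#' (year 2000) water-column oxygen minimum, in mmol m-3; the coefficient of
#' variation normalizes it by the contemporary ensemble mean, in percent.
#'
#' @param archive An `ensemble_archive` containing slice 2000.
#' @param unweighted Use equal member weights.
#' @param eps Mean guard for the CV denominator, mmol m-3.
#' @param slice Slice year, default 2000.
#' @return List with per-gridpoint `mean`, `spread` (mmol m-3) and `cv` (%).
#' @export
contemporary_spread_maps <- function(archive, unweighted = FALSE,
                                     eps = 1e-6, slice = 2000) {
  stopifnot(inherits(archive, "ensemble_archive"))
  s <- as.character(slice)
  if (!s %in% dimnames(archive$min_o2)[[3]])
    stop(sprintf("time slice %s not present in the archive", s),
         call. = FALSE)
  w <- archive_weights(archive, unweighted)
  mom <- weighted_row_moments(archive$min_o2[, , s], w)
  cv <- rep(NA_real_, length(mom$mean))
  ok <- abs(mom$mean) > eps
  cv[ok] <- 100 * mom$sd[ok] / abs(mom$mean[ok])
  list(mean = mom$mean, spread = mom$sd, cv = cv)
}

#' Mask gridpoints whose ensemble variance is very small
#'
#' Sensitivity fractions are meaningless where there is (almost) no
#' variance to decompose; following the mapping convention, gridpoints
#' whose ensemble standard deviation falls below a fraction (default 6%)
#' of the local mean magnitude are masked out.
#'
#' @param sobol A `sobol_field` (its `total_variance` supplies the sd).
#' @param mean_field Per-gridpoint ensemble mean of the decomposed output.
#' @param threshold_frac Mask threshold as sd / |mean| (default 0.06).
#' @return Logical vector, `TRUE` where the gridpoint is masked.
#' @export
mask_low_variance <- function(sobol, mean_field, threshold_frac = 0.06) {
  stopifnot(inherits(sobol, "sobol_field"))
  if (length(mean_field) != length(sobol$total_variance))
    stop("'mean_field' does not match the Sobol field gridpoints",
         call. = FALSE)
  sqrt(sobol$total_variance) < threshold_frac * abs(mean_field)
}

#' All map-level diagnostics in one pass
#'
#' Convenience wrapper computing the ensemble mean change (projected minus
#' preindustrial), its noise-to-signal map, the contemporary spread and
#' coefficient of variation, and the low-variance mask for a Sobol field.
#'
#' @param archive An `ensemble_archive`.
#' @param sobol Optional `sobol_field` used for the low-variance mask (if
#'   `NULL` the mask entries are `NA`).
#' @param mask_mean_field Mean field matching `sobol` for the mask
#'   threshold; defaults to the contemporary ensemble mean.
#' @param unweighted Use equal member weights throughout.
#' @param eps Mean-amplitude guard for ratio maps, mmol m-3.
#' @param threshold_frac Low-variance mask threshold.
#' @return An object of class `diagnostic_maps`: per-gridpoint
#'   `mean_change`, `noise_to_signal` (%), `contemporary_mean`,
#'   `contemporary_spread`, `contemporary_cv` (%), `low_variance_mask`.
#' @export
diagnostic_maps <- function(archive, sobol = NULL, mask_mean_field = NULL,
                            unweighted = FALSE, eps = 1e-6,
                            threshold_frac = 0.06) {
  w <- archive_weights(archive, unweighted)
  change <- change_field(archive, 1850, 2100)
  mom <- weighted_row_moments(change, w)
  contemp <- contemporary_spread_maps(archive, unweighted, eps)
  mask <- if (is.null(sobol)) {
    rep(NA, length(mom$mean))
  } else {
    mf <- if (is.null(mask_mean_field)) contemp$mean else mask_mean_field
    mask_low_variance(sobol, mf, threshold_frac)
  }
  structure(
    list(mean_change = mom$mean,
         noise_to_signal = noise_to_signal(change, w, eps),
         contemporary_mean = contemp$mean,
         contemporary_spread = contemp$spread,
         contemporary_cv = contemp$cv,
         low_variance_mask = mask),
    class = "diagnostic_maps"
  )
}

#' Define a set of non-overlapping gridpoint regions
#'
#' Regions are named collections of gridpoint (column) indices; for the
#' synthetic world they are typically regime labels, for an external
#' archive they come from lat/lon boxes resolved to gridpoint indices by
#' the reader.
#'
#' @param ... Named integer vectors of gridpoint indices, or a single
#'   named list of such vectors.
#' @return A named list of class `region_set`.
#' @export
region_set <- function(...) {
  regions <- list(...)
  if (length(regions) == 1L && is.list(regions[[1]]) &&
      !is.numeric(regions[[1]])) regions <- regions[[1]]
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("every region must be named", call. = FALSE)
  for (nm in names(regions)) {
    if (length(regions[[nm]]) == 0)
      stop(sprintf("region '%s' is empty", nm), call. = FALSE)
  }
  all_idx <- unlist(regions)
  if (anyDuplicated(all_idx))
    stop("regions overlap within one region set", call. = FALSE)
  structure(regions, class = "region_set")
}

#' Regions from the synthetic world's regime labels
#'
#' @param archive An `ensemble_archive` produced by [run_ensemble()].
#' @return A `region_set` with one region per regime.
#' @export
regime_regions <- function(archive) {
  stopifnot(inherits(archive, "ensemble_archive"))
  reg <- archive$columns$regime
  region_set(split(seq_along(reg), reg))
}

#' Regional averages of Sobol variance fractions
#'
#' Unweighted arithmetic mean of the per-gridpoint percentage indices over
#' the unmasked gridpoints of each region (percentages are averaged, not
#' variances pooled). A region whose gridpoints are all masked yields a row
#' of `NA` and a warning.
#'
#' @param sobol A `sobol_field`.
#' @param regions A `region_set`.
#' @param mask Optional logical mask (e.g. from [mask_low_variance()]);
#'   masked gridpoints are excluded from the averages.
#' @return Data frame with one row per region: the seven variance
#'   fractions in percent, the mean total variance and the number of
#'   contributing gridpoints.
#' @export
regional_average <- function(sobol, regions, mask = NULL) {
  stopifnot(inherits(sobol, "sobol_field"), inherits(regions, "region_set"))
  G <- length(sobol$total_variance)
  if (is.null(mask)) mask <- rep(FALSE, G)
  rows <- lapply(names(regions), function(nm) {
    idx <- regions[[nm]]
    idx <- idx[!mask[idx] & !is.na(sobol$fractions[1, idx])]
    if (length(idx) == 0) {
      message(sprintf("region '%s' has no unmasked gridpoints", nm))
      vals <- rep(NA_real_, nrow(sobol$fractions))
      tv <- NA_real_
    } else {
      vals <- rowMeans(sobol$fractions[, idx, drop = FALSE])
      tv <- mean(sobol$total_variance[idx])
    }
    out <- data.frame(region = nm, n_gridpoints = length(idx))
    out[rownames(sobol$fractions)] <- as.list(vals)
    out$variance_total <- tv
    out
  })
  do.call(rbind, rows)
}

#' Benchmarking scores: where do observations best constrain a parameter?
#'
#' A gridpoint is a good benchmarking location for a parameter when the
#' contemporary ensemble spread there is high and attributable
#' predominantly to that parameter. The score is the parameter's
#' contemporary main effect (in percent) at gridpoints whose spread exceeds
#' a configurable quantile of the unmasked spread distribution; everywhere
#' else (low spread, masked, undefined) the score is missing.
#'
#' @param sobol_contemporary `sobol_field` of the contemporary minimum.
#' @param spread Per-gridpoint contemporary ensemble spread, mmol m-3.
#' @param mask Logical low-variance mask.
#' @param spread_quantile Spread eligibility quantile over unmasked
#'   gridpoints (default 0.5, the median).
#' @param top_k Number of top gridpoints listed per parameter.
#' @return An object of class `benchmark_scores`: `scores` (3 x n_grid
#'   matrix, rows `w`, `kappa`, `a`, `NA` where ineligible),
#'   `spread_threshold`, and `top`, a data frame listing the `top_k`
#'   highest-scoring gridpoints per parameter (the benchmarking regions).
#' @export
benchmark_scores <- function(sobol_contemporary, spread, mask,
                             spread_quantile = 0.5, top_k = 5) {
  stopifnot(inherits(sobol_contemporary, "sobol_field"))
  G <- length(sobol_contemporary$total_variance)
  stopifnot(length(spread) == G, length(mask) == G)
  eligible_pool <- spread[!mask & !is.na(sobol_contemporary$fractions[1, ])]
  thr <- stats::quantile(eligible_pool, spread_quantile, names = FALSE,
                         na.rm = TRUE)
  eligible <- !mask & spread > thr &
    !is.na(sobol_contemporary$fractions[1, ])
  scores <- sobol_contemporary$fractions[c("S_w", "S_kappa", "S_a"), ,
                                         drop = FALSE]
  rownames(scores) <- c("w", "kappa", "a")
  scores[, !eligible] <- NA_real_
  top <- do.call(rbind, lapply(rownames(scores), function(p) {
    sc <- scores[p, ]
    ord <- order(sc, decreasing = TRUE, na.last = NA)
    ord <- utils::head(ord, top_k)
    if (length(ord) == 0) return(NULL)
    data.frame(parameter = p, gridpoint = ord, score = sc[ord],
               spread = spread[ord], row.names = NULL)
  }))
  structure(list(scores = scores, spread_threshold = thr, top = top),
            class = "benchmark_scores")
}

#' Spatial decoupling of contemporary and projected uncertainty
#'
#' Rank correlation (Spearman) between the contemporary coefficient of
#' variation and the projected-change noise-to-signal ratio across
#' gridpoints where both are defined. A value well below 1 indicates that
#' locations where the model ensemble disagrees today are not necessarily
#' those where its projections are most uncertain.
#'
#' @param maps A `diagnostic_maps` object.
#' @return Spearman rank correlation (scalar).
#' @export
uncertainty_rank_correlation <- function(maps) {
  stopifnot(inherits(maps, "diagnostic_maps"))
  ok <- !is.na(maps$contemporary_cv) & !is.na(maps$noise_to_signal)
  stats::cor(maps$contemporary_cv[ok], maps$noise_to_signal[ok],
             method = "spearman")
}

#' @export
print.diagnostic_maps <- function(x, ...) {
  cat(sprintf("Diagnostic maps over %d gridpoints\n", length(x$mean_change)))
  cat(sprintf("  mean change (1850 -> 2100): %.2f .. %.2f mmol m-3\n",
              min(x$mean_change), max(x$mean_change)))
  cat(sprintf("  noise-to-signal: median %.1f%% (%d undefined)\n",
              stats::median(x$noise_to_signal, na.rm = TRUE),
              sum(is.na(x$noise_to_signal))))
  cat(sprintf("  contemporary CV: median %.1f%%; %d gridpoints masked\n",
              stats::median(x$contemporary_cv, na.rm = TRUE),
              sum(x$low_variance_mask, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.benchmark_scores <- function(x, ...) {
  cat(sprintf(
    "Benchmarking scores (spread threshold %.3g mmol m-3):\n",
    x$spread_threshold))
  print(x$top)
  invisible(x)
}
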
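#' Define an uncertain model parameter
#'
#' The three biogeochemical parameters treated as uncertain are modelled as
#' truncated Gaussians: a mean in physical units, a standard deviation given
#' as a fraction of the mean, and a floor below which sampled or collocated
#' values are clipped (negative or near-zero rates are not physical).
#'
#' @param name One of `"w"` (detritus sinking speed, m day^-1),
#'   `"kappa"` (vertical background diffusivity, m^2 s^-1) or
#'   `"a"` (maximum phytoplankton growth rate, day^-1).
#' @param mean Prior mean, physical units. Must be positive.
#' @param rel_sd Prior standard deviation as a fraction of the mean,
#'   in (0, 1).
#' @param floor Minimum admissible physical value after truncation;
#'   must satisfy `0 <= floor < mean`. Defaults to 5% of the mean.
#' @return An object of class `uncertain_parameter`.
#' @examples
#' uncertain_parameter("w", mean = 15, rel_sd = 0.5)
#' @export
uncertain_parameter <- function(name, mean, rel_sd, floor = 0.05 * mean) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("w", "kappa", "a")) {
    stop("'name' must be one of \"w\", \"kappa\", \"a\"", call. = FALSE)
  }
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("'mean' must be a single positive number", call. = FALSE)
  if (!is.numeric(rel_sd) || length(rel_sd) != 1L ||
      rel_sd <= 0 || rel_sd >= 1)
    stop("'rel_sd' must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(floor) || length(floor) != 1L || floor < 0 || floor >= mean)
    stop("'floor' must satisfy 0 <= floor < mean", call. = FALSE)
  structure(
    list(name = name, mean = mean, rel_sd = rel_sd, floor = floor),
    class = "uncertain_parameter"
  )
}

#' Canonical three-parameter set
#'
#' Bundles the three uncertain parameters in the fixed canonical order
#' (w, kappa, a) used by every multi-index downstream.
#'
#' @param w,kappa,a `uncertain_parameter` objects with the matching names.
#' @return An object of class `parameter_set`: a list of the three
#'   parameters in canonical order.
#' @seealso [default_parameter_set()]
#' @export
parameter_set <- function(w, kappa, a) {
  ps <- list(w = w, kappa = kappa, a = a)
  for (nm in names(ps)) {
    p <- ps[[nm]]
    if (!inherits(p, "uncertain_parameter"))
      stop("all arguments must be 'uncertain_parameter' objects", call. = FALSE)
    if (p$name != nm)
      stop(sprintf("parameter in slot '%s' is named '%s'", nm, p$name),
           call. = FALSE)
  }
  structure(ps, class = "parameter_set")
}

#' Default priors for the three uncertain parameters
#'
#' Relative standard deviations follow the uncertainty assessment underlying
#' the ensemble design: 50% of the mean for the sinking speed and the
#' background diffusivity, 25% for the maximum growth rate. Mean values are
#' order-of-magnitude typical for coarse-resolution pelagic biogeochemical
#' models; every number is overridable through the configuration file.
#'
#' @param w_mean Sinking speed mean, m day^-1.
#' @param kappa_mean Background diffusivity mean, m^2 s^-1.
#' @param a_mean Maximum growth rate mean, day^-1.
#' @param floor_frac Truncation floor as a fraction of each mean.
#' @return A `parameter_set`.
#' @export
default_parameter_set <- function(w_mean = 15, kappa_mean = 3e-5,
                                  a_mean = 0.6, floor_frac = 0.05) {
  parameter_set(
    w     = uncertain_parameter("w", w_mean, 0.5, floor_frac * w_mean),
    kappa = uncertain_parameter("kappa", kappa_mean, 0.5,
                                floor_frac * kappa_mean),
    a     = uncertain_parameter("a", a_mean, 0.25, floor_frac * a_mean)
  )
}

#' Map a physical parameter value to its standardized coordinate
#'
#' The standardized coordinate is the value's position in prior standard
#' deviations from the prior mean, i.e. `(x - mean) / (rel_sd * mean)`.
#'
#' @param p An `uncertain_parameter`.
#' @param x Physical value(s).
#' @return Standardized coordinate(s), dimensionless.
#' @export
standardize <- function(p, x) {
  stopifnot(inherits(p, "uncertain_parameter"))
  (x - p$mean) / (p$rel_sd * p$mean)
}

#' Map a standardized coordinate to a physical parameter value
#'
#' Inverse of [standardize()] on the untruncated branch; values that would
#' fall below the parameter's floor are clipped to the floor, mirroring the
#' truncation of occasional negative and very small parameter draws.
#'
#' @param p An `uncertain_parameter`.
#' @param xi Standardized coordinate(s).
#' @return Physical value(s), always `>= p$floor`.
#' @export
destandardize <- function(p, xi) {
  stopifnot(inherits(p, "uncertain_parameter"))
  pmax(p$mean * (1 + p$rel_sd * xi), p$floor)
}

#' @export
print.uncertain_parameter <- function(x, ...) {
  units <- c(w = "m day-1", kappa = "m2 s-1", a = "day-1")[x$name]
  cat(sprintf(
    "Uncertain parameter '%s': mean %g %s, sd %.0f%% of mean, floor %g\n",
    x$name, x$mean, units, 100 * x$rel_sd, x$floor))
  invisible(x)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Parameter set (canonical order w, kappa, a):\n")
  for (p in x) print(p)
  invisible(x)
}
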
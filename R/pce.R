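#' Fit per-gridpoint Polynomial Chaos Expansions by spectral projection
#'
#' Non-intrusive discrete projection on the collocation design: each
#' coefficient is the quadrature approximation of the inner product of the
#' output with an orthonormal Hermite basis function,
#' `c_alpha(g) = sum_q w_q Y_q(g) psi_alpha(xi_q)`. On a full tensor
#' Gauss-Hermite design this projection is exact for outputs that are
#' polynomials of total degree at most `max_order` (given enough points per
#' dimension), and the zero-index coefficient equals the weighted ensemble
#' mean.
#'
#' @param design A `quadrature_design`.
#' @param outputs Numeric matrix, one row per design run and one column per
#'   gridpoint (a vector is treated as a single gridpoint). No missing
#'   values: masked gridpoints must be excluded beforehand.
#' @param max_order Maximum total polynomial order retained (default 3).
#' @param output_name Label carried through to maps and files.
#' @return An object of class `pce_field`: list with `basis` (multi-index
#'   matrix, constant term first), `coeffs` (n_basis x n_grid matrix) and
#'   `output_name`.
#' @export
fit_pce <- function(design, outputs, max_order = 3, output_name = "output") {
  stopifnot(inherits(design, "quadrature_design"))
  if (is.null(dim(outputs))) outputs <- matrix(outputs, ncol = 1)
  R <- nrow(design$nodes_std)
  if (nrow(outputs) != R)
    stop(sprintf("'outputs' has %d rows but the design has %d runs",
                 nrow(outputs), R), call. = FALSE)
  if (anyNA(outputs) || any(!is.finite(outputs)))
    stop("'outputs' contains missing or non-finite values", call. = FALSE)
  basis <- multi_index_basis(max_order)
  psi <- vapply(seq_len(nrow(basis)),
                function(k) basis_eval(basis[k, ], design$nodes_std),
                numeric(R))                      # R x n_basis
  coeffs <- t(psi * design$weights) %*% outputs  # n_basis x n_grid
  dimnames(coeffs) <- list(NULL, colnames(outputs))
  structure(
    list(basis = basis, coeffs = coeffs, max_order = max_order,
         output_name = output_name),
    class = "pce_field"
  )
}

#' Evaluate a fitted PCE at standardized coordinates
#'
#' @param pce A `pce_field`.
#' @param xi Standardized coordinates, length-3 vector or R x 3 matrix.
#' @return Matrix of predictions, one row per row of `xi`, one column per
#'   gridpoint.
#' @export
pce_eval <- function(pce, xi) {
  stopifnot(inherits(pce, "pce_field"))
  if (is.null(dim(xi))) xi <- matrix(xi, nrow = 1)
  psi <- vapply(seq_len(nrow(pce$basis)),
                function(k) basis_eval(pce$basis[k, ], xi),
                numeric(nrow(xi)))
  if (is.null(dim(psi))) psi <- matrix(psi, nrow = nrow(xi))
  psi %*% pce$coeffs
}

# Sobol group key of a multi-index: the set of parameters with non-zero
# order, e.g. (2,1,0) -> "w:kappa". The constant term maps to "".
sobol_group <- function(basis) {
  apply(basis, 1, function(a)
    paste(c("w", "kappa", "a")[a > 0], collapse = ":"))
}

.sobol_terms <- c("S_w", "S_kappa", "S_a",
                  "S_w_kappa", "S_w_a", "S_kappa_a", "S_w_kappa_a")
.sobol_groups <- c("w", "kappa", "a", "w:kappa", "w:a", "kappa:a",
                   "w:kappa:a")

#' Sobol variance decomposition of a PCE
#'
#' For an expansion in an orthonormal basis the output variance is the sum
#' of squared non-constant coefficients, `D = sum_{alpha != 0} c_alpha^2`,
#' and the variance fraction attributable to a parameter subset U collects
#' exactly those coefficients whose non-zero index positions equal U. This
#' yields the three main effects, the three pairwise interactions and the
#' triple interaction, expressed in percent; together they always account
#' for 100% of the variance.
#'
#' Gridpoints with zero total variance get `NA` fractions (a sentinel, never
#' 0: a zero would falsely assert insensitivity).
#'
#' @param pce A `pce_field`.
#' @param zero_tol Relative threshold below which the total variance is
#'   treated as numerically zero (relative to `max(c0^2, 1)`, guarding
#'   against projection roundoff of constant fields).
#' @return An object of class `sobol_field`: list with `total_variance`
#'   (per-gridpoint, squared output units) and `fractions`, a 7 x n_grid
#'   matrix with rows `S_w`, `S_kappa`, `S_a`, `S_w_kappa`, `S_w_a`,
#'   `S_kappa_a`, `S_w_kappa_a` in percent.
#' @export
sobol_decompose <- function(pce, zero_tol = 1e-24) {
  stopifnot(inherits(pce, "pce_field"))
  grp <- sobol_group(pce$basis)
  sq <- pce$coeffs^2
  D <- colSums(sq[grp != "", , drop = FALSE])
  fractions <- matrix(NA_real_, nrow = length(.sobol_groups), ncol = length(D),
                      dimnames = list(.sobol_terms, colnames(pce$coeffs)))
  ok <- D > zero_tol * pmax(sq[1, ], 1)
  D[!ok] <- 0
  for (i in seq_along(.sobol_groups)) {
    contrib <- colSums(sq[grp == .sobol_groups[i], , drop = FALSE])
    fractions[i, ok] <- 100 * contrib[ok] / D[ok]
  }
  structure(
    list(total_variance = D, fractions = fractions,
         output_name = pce$output_name),
    class = "sobol_field"
  )
}

#' Weighted ensemble mean and standard deviation per gridpoint
#'
#' Ensemble members sit at collocation nodes, not equiprobable samples, so
#' moments are taken with the quadrature weights:
#' `mean = sum_q w_q Y_q`, `var = sum_q w_q (Y_q - mean)^2`. Passing
#' `unweighted = TRUE` uses equal weights instead, for comparison with
#' naive ensemble statistics.
#'
#' @param design A `quadrature_design`.
#' @param outputs Run x gridpoint matrix (or vector for one gridpoint).
#' @param unweighted Use equal member weights instead of quadrature weights.
#' @return List with numeric vectors `mean` and `sd` (one entry per
#'   gridpoint).
#' @export
ensemble_moments <- function(design, outputs, unweighted = FALSE) {
  stopifnot(inherits(design, "quadrature_design"))
  if (is.null(dim(outputs))) outputs <- matrix(outputs, ncol = 1)
  R <- nrow(design$nodes_std)
  if (nrow(outputs) != R)
    stop(sprintf("'outputs' has %d rows but the design has %d runs",
                 nrow(outputs), R), call. = FALSE)
  w <- if (unweighted) rep(1 / R, R) else design$weights
  m <- colSums(outputs * w)
  v <- colSums((outputs - rep(m, each = R))^2 * w)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

#' @export
print.pce_field <- function(x, ...) {
  cat(sprintf("PCE field '%s': %d basis terms (order <= %d), %d gridpoints\n",
              x$output_name, nrow(x$basis), x$max_order, ncol(x$coeffs)))
  invisible(x)
}

#' @export
print.sobol_field <- function(x, ...) {
  cat(sprintf("Sobol field '%s': %d gridpoints (%d with zero variance)\n",
              x$output_name, length(x$total_variance),
              sum(x$total_variance == 0)))
  means <- rowMeans(x$fractions, na.rm = TRUE)
  cat("Mean variance fractions (%):\n")
  print(round(means, 2))
  invisible(x)
}
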
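#' Probabilists' Hermite polynomial He_n
#'
#' Evaluated by the three-term recurrence He_0 = 1, He_1 = x,
#' He_{n+1}(x) = x He_n(x) - n He_{n-1}(x). This family is orthogonal under
#' the standard-normal weight with E[He_m He_n] = n! delta_mn, which makes it
#' the natural basis when uncertain inputs are modelled as Gaussians.
#'
#' @param n Polynomial order, non-negative integer.
#' @param x Numeric vector of evaluation points.
#' @return `He_n(x)`, same length as `x`.
#' @export
hermite <- function(n, x) {
  if (length(n) != 1L || n < 0 || n != round(n))
    stop("'n' must be a single non-negative integer", call. = FALSE)
  if (n == 0) return(rep(1, length(x)))
  if (n == 1) return(x)
  hm1 <- rep(1, length(x))
  h <- x
  for (k in 1:(n - 1)) {
    hp1 <- x * h - k * hm1
    hm1 <- h
    h <- hp1
  }
  h
}

#' Total-degree multi-index basis
#'
#' All triples of non-negative integer orders (alpha_w, alpha_kappa, alpha_a)
#' with total order at most `max_order`, in graded ordering (total order
#' ascending, lexicographic within a grade), so the constant term comes
#' first. For `max_order = 3` the basis has 20 members.
#'
#' @param max_order Maximum total polynomial order (default 3).
#' @return Integer matrix with one row per multi-index and columns
#'   `w`, `kappa`, `a`.
#' @export
multi_index_basis <- function(max_order = 3) {
  if (max_order < 0) stop("'max_order' must be >= 0", call. = FALSE)
  g <- expand.grid(a = 0:max_order, kappa = 0:max_order, w = 0:max_order)
  g <- g[rowSums(g) <= max_order, c("w", "kappa", "a")]
  g <- g[order(rowSums(g), g$w, g$kappa, g$a), ]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("w", "kappa", "a"))
  storage.mode(m) <- "integer"
  m
}

#' Orthonormal tensor Hermite basis function
#'
#' psi_alpha(xi) = prod_i He_{alpha_i}(xi_i) / sqrt(alpha_i!), orthonormal
#' under the product standard-normal measure.
#'
#' @param alpha Integer multi-index of length 3.
#' @param xi Standardized coordinates: a length-3 vector or an R x 3 matrix.
#' @return Numeric vector with one value per row of `xi`.
#' @export
basis_eval <- function(alpha, xi) {
  if (length(alpha) != 3L || any(alpha < 0))
    stop("'alpha' must be a length-3 non-negative multi-index", call. = FALSE)
  if (is.null(dim(xi))) xi <- matrix(xi, nrow = 1)
  out <- rep(1, nrow(xi))
  for (i in 1:3) {
    out <- out * hermite(alpha[i], xi[, i]) / sqrt(factorial(alpha[i]))
  }
  out
}

# Golub-Welsch: nodes/weights of the n-point Gauss rule for the standard
# normal weight, from the symmetric Jacobi matrix of the probabilists'
# Hermite recurrence (off-diagonal sqrt(1..n-1)). Weights are the squared
# first components of the eigenvectors; nodes are symmetrized to remove
# eigensolver roundoff.
gauss_hermite_prob <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  J <- diag(0, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- e$values[ord]
  weights <- e$vectors[1, ord]^2
  nodes <- (nodes - rev(nodes)) / 2
  weights <- (weights + rev(weights)) / 2
  weights <- weights / sum(weights)
  list(nodes = nodes, weights = weights)
}

#' Tensor Gauss-Hermite collocation design
#'
#' Builds the full tensor product of the one-dimensional Gauss rule for the
#' standard-normal weight in the three standardized parameter directions,
#' then maps nodes to physical units via [destandardize()] (which applies
#' the truncation floors). With the default 5 points per dimension the
#' design has 125 runs; a 5-point rule integrates polynomials up to degree
#' 9 exactly, ample for a third-order expansion.
#'
#' Truncation is applied to the collocation nodes only; quadrature weights
#' are left unchanged, which corresponds to running a designed simulation
#' whose physical inputs were clipped at the floor.
#'
#' @param ps A `parameter_set`.
#' @param points_per_dim Number of quadrature points per dimension (>= 1).
#' @return An object of class `quadrature_design`: list with `nodes_std`
#'   (R x 3), `nodes_phys` (R x 3), `weights` (length R, summing to 1) and
#'   `points_per_dim`.
#' @export
build_design <- function(ps, points_per_dim = 5) {
  stopifnot(inherits(ps, "parameter_set"))
  if (points_per_dim < 1) stop("'points_per_dim' must be >= 1", call. = FALSE)
  gh <- gauss_hermite_prob(as.integer(points_per_dim))
  # w varies slowest, a fastest: row order matches the graded index order
  grid <- expand.grid(a = seq_along(gh$nodes), kappa = seq_along(gh$nodes),
                      w = seq_along(gh$nodes))[, c("w", "kappa", "a")]
  nodes_std <- cbind(w = gh$nodes[grid$w], kappa = gh$nodes[grid$kappa],
                     a = gh$nodes[grid$a])
  weights <- gh$weights[grid$w] * gh$weights[grid$kappa] * gh$weights[grid$a]
  weights <- weights / sum(weights)
  nodes_phys <- cbind(
    w     = destandardize(ps$w, nodes_std[, "w"]),
    kappa = destandardize(ps$kappa, nodes_std[, "kappa"]),
    a     = destandardize(ps$a, nodes_std[, "a"])
  )
  structure(
    list(nodes_std = nodes_std, nodes_phys = nodes_phys,
         weights = weights, points_per_dim = as.integer(points_per_dim),
         parameter_set = ps),
    class = "quadrature_design"
  )
}

#' @export
print.quadrature_design <- function(x, ...) {
  cat(sprintf(
    "Gauss-Hermite collocation design: %d runs (%d^3), weights sum %.12f\n",
    nrow(x$nodes_std), x$points_per_dim, sum(x$weights)))
  invisible(x)
}
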
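# Independent oracles used by the tests. Everything here is written
# against first principles (closed forms, Monte-Carlo estimators), never
# through the package's own PCE/quadrature code paths.

# Closed-form probabilists' Hermite polynomials, orders 0..3.
he_closed <- list(
  function(x) rep(1, length(x)),
  function(x) x,
  function(x) x^2 - 1,
  function(x) x^3 - 3 * x
)

# Orthonormal tensor basis function from the closed forms.
psi_closed <- function(alpha, xi) {
  out <- rep(1, nrow(xi))
  for (i in 1:3)
    out <- out * he_closed[[alpha[i] + 1]](xi[, i]) / sqrt(factorial(alpha[i]))
  out
}

# Monte-Carlo projection of f onto the orthonormal basis function psi_alpha
# under the independent standard-normal measure.
mc_projection <- function(f, alpha, n = 1e6, seed = 1) {
  set.seed(seed)
  xi <- matrix(rnorm(3 * n), ncol = 3)
  y <- f(xi) * psi_closed(alpha, xi)
  list(estimate = mean(y), se = stats::sd(y) / sqrt(n))
}

# Random polynomial of total degree <= 3 in monomials (not Hermite terms),
# with standard-normal coefficients. Returns f(xi_matrix) -> vector.
random_cubic <- function(seed) {
  set.seed(seed)
  mono <- expand.grid(i = 0:3, j = 0:3, k = 0:3)
  mono <- mono[rowSums(mono) <= 3, ]
  coef <- rnorm(nrow(mono))
  function(xi) {
    out <- numeric(nrow(xi))
    for (m in seq_len(nrow(mono))) {
      out <- out + coef[m] * xi[, 1]^mono$i[m] * xi[, 2]^mono$j[m] *
        xi[, 3]^mono$k[m]
    }
    out
  }
}

# Saltelli-type Monte-Carlo Sobol estimator for a 3-input function of
# independent standard normals. Returns main effects, closed and
# interaction second-order indices, and the residual triple interaction,
# all as fractions (not %), with standard errors.
saltelli_sobol <- function(f, n = 1e5, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(3 * n), ncol = 3)
  B <- matrix(rnorm(3 * n), ncol = 3)
  fA <- f(A); fB <- f(B)
  f0 <- mean(c(fA, fB))
  V <- stats::var(c(fA, fB))
  fAB <- lapply(1:3, function(i) { M <- A; M[, i] <- B[, i]; f(M) })
  fBA <- lapply(1:3, function(i) { M <- B; M[, i] <- A[, i]; f(M) })

  S <- numeric(3); S_se <- numeric(3)
  for (i in 1:3) {
    elem <- fB * (fAB[[i]] - fA)           # Saltelli 2010 elementary terms
    S[i] <- mean(elem) / V
    S_se[i] <- stats::sd(elem) / sqrt(n) / V
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  S2 <- numeric(3); S2_se <- numeric(3)
  for (p in seq_along(pairs)) {
    i <- pairs[[p]][1]; j <- pairs[[p]][2]
    elem <- fAB[[i]] * fBA[[j]] - fA * fB  # closed V_ij + noise
    Vij_closed <- mean(elem) / V
    se_closed <- stats::sd(elem) / sqrt(n) / V
    S2[p] <- Vij_closed - S[i] - S[j]
    S2_se[p] <- se_closed + S_se[i] + S_se[j]  # conservative
  }
  S3 <- 1 - sum(S) - sum(S2)
  S3_se <- sum(S_se) + sum(S2_se)
  list(main = S, main_se = S_se, pair = S2, pair_se = S2_se,
       triple = S3, triple_se = S3_se, variance = V)
}

# Reference 5-point Gauss rule for the standard-normal weight, frozen from
# an independent root-finding computation (scaled physicists' rule).
gh5_nodes_ref <- c(-2.8569700138728056, -1.3556261799742675, 0,
                   1.3556261799742675, 2.8569700138728056)
gh5_weights_ref <- c(0.011257411327720656, 0.22207592200561264,
                     0.5333333333333333, 0.22207592200561264,
                     0.011257411327720656)

# Small world/archive fixture shared by diagnostics and IO tests.
small_fixture <- function(n_columns = 12, seed = 7, points_per_dim = 3) {
  cfg <- toy_ocean_config(n_columns = n_columns)
  design <- build_design(default_parameter_set(), points_per_dim)
  world <- generate_world(cfg, seed)
  archive <- run_ensemble(design, world, column_grid(), cfg)
  list(cfg = cfg, design = design, world = world, archive = archive)
}
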
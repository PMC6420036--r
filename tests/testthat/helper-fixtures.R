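# shared fixtures: defaults and small instances used across test files

default_params <- function() model_parameters()

small_params <- function(z_hat = 5, ...) model_parameters(z_hat = z_hat, ...)

# brute-force binomial pmf from factorials (independent of dbinom)
brute_binom <- function(z, n, p) {
  choose_nz <- factorial(n) / (factorial(z) * factorial(n - z))
  choose_nz * p^z * (1 - p)^(n - z)
}

# hand-assembled generator for z_hat = 3, following the master equation
# term by term (replication shift, division loss, division inflow)
hand_generator_3 <- function(p, b = 1.2, beta0 = 1) {
  z_hat <- 3
  beta <- beta0 * (1 - (1:3) / z_hat)          # 2/3, 1/3, 0
  repl <- b * (1:3) * (1 - (1:3) / z_hat)
  g <- function(z, z0, pp) brute_binom(z, z0, pp)
  k <- function(z, z0, pp) g(z, z0, pp) + g(z0 - z, z0, pp)
  A <- matrix(0, 3, 3)
  for (z in 1:3) A[z, z] <- -repl[z] - beta[z]
  A[2, 1] <- A[2, 1] + repl[1]
  A[3, 2] <- A[3, 2] + repl[2]
  for (z0 in 1:3) {
    if (beta[z0] == 0) next
    for (z in 1:z0) A[z, z0] <- A[z, z0] + k(z, z0, p[z0]) * beta[z0]
  }
  B <- vapply(1:3, function(z0) {
    if (beta[z0] == 0) 0 else k(0, z0, p[z0]) * beta[z0]
  }, numeric(1))
  list(A = A, B = B, beta = beta)
}

# dominant eigenvalue by power iteration on a shifted matrix: independent
# oracle for the dense eigendecomposition route
power_lambda1 <- function(A, tol = 1e-12, max_iter = 100000) {
  shift <- max(abs(diag(A))) + 1
  M <- A + shift * diag(nrow(A))
  v <- rep(1, nrow(A))
  lam <- 0
  for (i in seq_len(max_iter)) {
    w <- M %*% v
    lam_new <- sum(w * v) / sum(v * v)
    v <- as.numeric(w) / sqrt(sum(w^2))
    if (abs(lam_new - lam) < tol) break
    lam <- lam_new
  }
  lam_new - shift
}

# cached default-parameter ESS so several tests can share one optimization
ess_cache <- new.env(parent = emptyenv())

cached_default_ess <- function() {
  if (is.null(ess_cache$ess)) {
    ess_cache$ess <- multi_start_ess(default_params(), n_starts = 3,
                                     seed = 42)
  }
  ess_cache$ess
}
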
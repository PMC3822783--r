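# Independent scalar oracles: straight transcriptions of the model's closed
# forms, kept free of package internals so rate/rhs tests are a dual route.
oracle_lambda <- function(N, lambda0, epsilon) lambda0 * exp(-N / epsilon)
oracle_delta <- function(N, delta0, rho) delta0 * exp(N / rho)
oracle_mu <- function(Y, mu_prime) mu_prime * Y

oracle_rhs <- function(X, Y, theta, p) {
  N <- X + Y
  lam <- oracle_lambda(N, p$lambda0, p$epsilon)
  del <- oracle_delta(N, p$delta0, p$rho)
  c(dX = theta + 2 * p$r * Y - lam * X - del * X,
    dY = lam * X - p$r * Y - p$mu_prime * Y^2)
}

# central finite differences of the exported rhs, oracle for the analytic
# Jacobian (relative step scaled to the state)
fd_jacobian <- function(X, Y, p, rel_h = 1e-6) {
  J <- matrix(0, 2, 2)
  s <- c(X, Y)
  for (j in 1:2) {
    h <- rel_h * max(1e-3 * p$cell_unit, abs(s[j]))
    up <- s
    dn <- s
    up[j] <- up[j] + h
    dn[j] <- max(dn[j] - h, 0)
    fu <- model_rhs(up[1], up[2], p)
    fd <- model_rhs(dn[1], dn[2], p)
    J[, j] <- c(fu$dX - fd$dX, fu$dY - fd$dY) / (up[j] - dn[j])
  }
  J
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual / expected - 1)), rel_tol)
}
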
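# Independent oracles used across the suite.  These deliberately use
# naive O(n^3) loops, brute-force enumeration, or reference libraries so
# they share no code with the package's implementation.

# plug-in H matrix by direct triple-loop summation
oracle_H <- function(phi, Phi, J, Tt) {
  n <- length(phi)
  H <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (k in 1:n) s <- s + J[k, j] * (Tt[k] <= Tt[i]) * phi[k]^2
    H[i, j] <- n * phi[j] * (Tt[j] <= Tt[i]) - n * s / Phi[j]
  }
  H
}

# truncated operator series sum_{r=0}^{c} A^r H, with explicit S and
# S^{-1} matrices; also reports the size of the last increment so tests
# can restrict to instances where the series has effectively converged
oracle_series_calA <- function(phi, Phi, J, Tt, H, c = 50000) {
  n <- length(phi)
  S <- outer(1:n, 1:n, ">=") * 1
  A <- S %*% diag(phi^2) %*% J %*% diag(1 / Phi^2) %*% t(J) %*% solve(S)
  # A has a unit eigenvalue (constant direction); the series converges
  # because H is orthogonal to it, but roundoff injects a tiny
  # non-decaying component, so stop once the increments plateau
  out <- H
  P <- H
  prev <- Inf
  for (r in seq_len(c)) {
    P <- A %*% P
    m <- max(abs(P))
    if (m < 1e-13 || m > 0.999 * prev) break
    out <- out + P
    prev <- m
  }
  # tie collapsing: row j -> last index of its tie group
  rl <- rle(Tt)
  rep_idx <- rep.int(cumsum(rl$lengths), rl$lengths)
  list(sum = out[rep_idx, , drop = FALSE], tail = prev)
}

# direct maximisation of the nonparametric likelihood over the simplex
# via an unconstrained softmax parameterisation
oracle_npmle_direct <- function(Tt, U, V) {
  n <- length(Tt)
  J <- outer(Tt, U, ">=") & outer(Tt, V, "<=")
  storage.mode(J) <- "double"
  negll <- function(theta) {
    phi <- exp(c(theta, 0))
    phi <- phi / sum(phi)
    Phi <- drop(crossprod(J, phi))
    -sum(log(phi) - log(Phi))
  }
  o <- stats::optim(rep(0, n - 1), negll, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  phi <- exp(c(o$par, 0))
  phi / sum(phi)
}

# brute-force strong connectivity by boolean transitive closure
oracle_strongly_connected <- function(adj) {
  n <- nrow(adj)
  reach <- (adj | diag(n)) != 0
  for (k in 1:n) reach <- reach | (reach %*% (reach * 1)) > 0
  all(reach & t(reach))
}

# hand-written partial-likelihood score for p = 1, no truncation, and a
# bisection root finder
oracle_cox_score1 <- function(beta, Tt, x) {
  n <- length(Tt)
  s <- 0
  for (i in 1:n) {
    rs <- which(Tt >= Tt[i])
    s <- s + x[i] - sum(x[rs] * exp(beta * x[rs])) / sum(exp(beta * x[rs]))
  }
  s
}

oracle_cox_bisect <- function(Tt, x, lo = -10, hi = 10) {
  stats::uniroot(function(b) oracle_cox_score1(b, Tt, x), c(lo, hi),
                 tol = 1e-12)$root
}

# quadrature oracle for pi(t) = P(U <= t <= V) and alpha under the main
# simulation design (U = 0.5 Beta(1,3), V = U + Beta(2,10) + 0.1)
oracle_pi_main <- function(t) {
  vapply(t, function(tt) {
    f <- function(u) {
      du <- stats::dbeta(u / 0.5, 1, 3) / 0.5
      du * (1 - stats::pbeta(tt - u - 0.1, 2, 10))
    }
    hi <- min(tt, 0.5)
    if (hi <= 0) return(0)
    stats::integrate(f, 0, hi, rel.tol = 1e-9)$value
  }, numeric(1))
}

# true marginal CDF of T under the main design (x1 ~ Bern(0.5),
# x2 ~ Unif(0,1), beta = (1,1), baseline 0.1 + 0.4 Beta(2, 1.5))
oracle_F_main <- function(t) {
  S0 <- function(s) 1 - stats::pbeta((s - 0.1) / 0.4, 2, 1.5)
  vapply(t, function(tt) {
    fx <- function(x2, x1) 1 - S0(tt)^exp(x1 + x2)
    0.5 * stats::integrate(fx, 0, 1, x1 = 0, rel.tol = 1e-9)$value +
      0.5 * stats::integrate(fx, 0, 1, x1 = 1, rel.tol = 1e-9)$value
  }, numeric(1))
}

# overall sampling probability alpha = integral of pi dF under the main
# design
oracle_alpha_main <- function() {
  f <- function(t) oracle_pi_main(t) *
    vapply(t, function(tt) {
      eps <- 1e-5
      (oracle_F_main(tt + eps) - oracle_F_main(tt - eps)) / (2 * eps)
    }, numeric(1))
  stats::integrate(f, 0.1, 0.5, rel.tol = 1e-7)$value
}

# small highly-truncated sample with a connected inclusion graph, for
# influence-oracle tests
make_truncated_sample <- function(n, seed) {
  set.seed(seed)
  repeat {
    d <- dt_sim_design(n = n)
    s <- dt_generate(d, seed = sample.int(1e8, 1))
    if (dt_strong_connected(dt_inclusion_matrix(s))$connected) return(s)
  }
}
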
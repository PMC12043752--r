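test_that("inclusion matrix evaluates the window indicator exactly", {
  s <- data.frame(T = c(1, 2, 3), U = c(0, 0, 2.5), V = c(1.5, 2.5, 3.5))
  J <- dt_inclusion_matrix(s)
  expect_equal(J, rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 1)),
               ignore_attr = TRUE)

  s2 <- dt_generate(dt_sim_design(n = 25), seed = 2)
  J2 <- dt_inclusion_matrix(s2)
  expect_true(all(diag(J2) == 1))   # forced by U <= T <= V

  wide <- data.frame(T = s2$T, U = rep(min(s2$T) - 1, 25),
                     V = rep(max(s2$T) + 1, 25))
  expect_true(all(dt_inclusion_matrix(wide) == 1))
})

test_that("strong connectedness agrees with brute-force transitive closure", {
  n <- 6
  all1 <- matrix(1, n, n)
  expect_true(dt_strong_connected(all1)$connected)

  blockJ <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
                  cbind(matrix(0, 3, 3), matrix(1, 3, 3)))
  sc <- dt_strong_connected(blockJ)
  expect_false(sc$connected)
  expect_equal(sc$n_components, 2L)

  set.seed(11)
  for (rep in 1:30) {
    m <- sample(3:8, 1)
    J <- matrix(rbinom(m * m, 1, 0.45), m, m)
    diag(J) <- 1
    expect_equal(dt_strong_connected(J)$connected,
                 oracle_strongly_connected(t(J)))
  }
})

test_that("EM solves the nonparametric likelihood and reduces correctly without truncation", {
  # no effective truncation: masses are uniform, a = 1, F = empirical CDF
  set.seed(4)
  Tt <- sort(runif(15))
  s <- dt_sample(Tt, rep(-1, 15), rep(2, 15))
  f <- dt_npmle(s)
  expect_equal(f$phi, rep(1 / 15, 15), tolerance = 1e-10)
  expect_equal(f$a, rep(1, 15), tolerance = 1e-10)
  expect_equal(dt_cdf(f, Tt), seq_len(15) / 15, tolerance = 1e-10)
  expect_equal(dt_cdf(f, min(Tt) - 1), 0)
  expect_equal(dt_cdf(f, max(Tt) + 1), 1)

  # hand-constructed truncated n = 4 sample vs direct simplex maximiser
  Tt <- c(1, 2, 3, 4)
  U <- c(0.5, 0.5, 1.5, 2.5)
  V <- c(2.5, 3.5, 4.5, 4.5)
  f4 <- dt_npmle(dt_sample(Tt, U, V))
  phi_direct <- oracle_npmle_direct(Tt, U, V)
  expect_equal(f4$phi, phi_direct, tolerance = 1e-6)

  # invariants on a simulated truncated fit
  s5 <- dt_generate(dt_sim_design(n = 60), seed = 9)
  f5 <- dt_npmle(s5)
  expect_equal(sum(f5$phi), 1, tolerance = 1e-10)
  expect_true(all(f5$phi > 0))
  expect_equal(f5$a, 1 / (f5$n * f5$phi), tolerance = 1e-7)
  expect_true(all(f5$Phi > 0 & f5$Phi <= 1 + 1e-12))
  # fixed point: 1/phi = J (1/Phi) up to the normalising constant n
  ratio <- (1 / f5$phi) / drop(f5$J %*% (1 / f5$Phi))
  expect_lt(diff(range(ratio)), 1e-6)

  # identifiability failure is a hard error
  bad <- dt_sample(c(1, 2, 10, 11), c(0.5, 0.5, 9, 9),
                   c(3, 3, 12, 12))
  expect_error(dt_npmle(bad), "strong connectedness")
})

test_that("EM iterations never decrease the nonparametric log likelihood", {
  s <- dt_generate(dt_sim_design(n = 50), seed = 12)
  ord <- order(s$T)
  J <- dt_inclusion_matrix(data.frame(T = s$T[ord], U = s$U[ord], V = s$V[ord]))
  n <- nrow(s)
  phi <- rep(1 / n, n)
  ll_old <- -Inf
  for (it in 1:50) {
    Phi <- drop(crossprod(J, phi))
    ll <- sum(log(phi) - log(Phi))
    expect_gte(ll, ll_old - 1e-12)
    ll_old <- ll
    phi <- 1 / drop(J %*% (1 / Phi))
    phi <- phi / sum(phi)
  }
})

test_that("selection probability matches its closed identities and the design truth", {
  s <- dt_generate(dt_sim_design(n = 80), seed = 21)
  f <- dt_npmle(s)
  # at observed event times a(t) equals 1/(n phi)
  expect_equal(dt_selection_probability(f, f$T), 1 / (f$n * f$phi),
               tolerance = 1e-7)
  # outside every window a(t) = 0 with a warning
  expect_warning(a0 <- dt_selection_probability(f, max(s$V) + 1), "a\\(t\\) = 0")
  expect_equal(a0, 0)

  # large-sample agreement with pi(t)/alpha computed by quadrature
  s2 <- dt_generate(dt_sim_design(n = 2000), seed = 31)
  f2 <- dt_npmle(s2)
  tg <- seq(quantile(s2$T, 0.02), quantile(s2$T, 0.98), length.out = 25)
  a_true <- oracle_pi_main(tg) / oracle_alpha_main()
  expect_lt(max(abs(dt_selection_probability(f2, tg) - a_true)), 0.05)
})

test_that("reweighting identity: CDF increments over an interval sum the interval masses", {
  s <- dt_generate(dt_sim_design(n = 70), seed = 41)
  f <- dt_npmle(s)
  br <- quantile(f$T, c(0.25, 0.8), names = FALSE)
  inc <- dt_cdf(f, br[2]) - dt_cdf(f, br[1])
  expect_equal(inc, sum(f$phi[f$T > br[1] & f$T <= br[2]]), tolerance = 1e-12)
})

test_that("NPMLE CDF error shrinks with the sample size", {
  sup_err <- function(n, seed) {
    errs <- vapply(1:6, function(k) {
      f <- dt_npmle(dt_generate(dt_sim_design(n = n), seed = seed + k))
      tg <- seq(0.12, 0.48, length.out = 40)
      max(abs(dt_cdf(f, tg) - oracle_F_main(tg)))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(sup_err(800, 600), sup_err(200, 500))
})
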
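test_that("four-subject fit equals the bisection root of the hand-written score", {
  Tt <- c(1, 2, 3, 4)
  x <- c(1, 0, 0, 1)
  s <- dt_sample(Tt, rep(0, 4), rep(5, 4), X = data.frame(x = x))
  fit <- dtcox(dtrunc(T, U, V) ~ x, data = s, weight = "unit")
  expect_equal(unname(coef(fit)), oracle_cox_bisect(Tt, x), tolerance = 1e-8)
})

test_that("score machinery is scale equivariant and refuses a constant covariate", {
  s <- dt_generate(dt_sim_design(n = 40), seed = 3)
  f <- dt_npmle(s)
  infl <- dt_influence(f)
  n <- f$n
  Z <- matrix(0, n, n)
  # doubling w scales the fitted score residuals but leaves the root alone
  e1 <- dtcox:::ipw_engine(f$T, f$X, f$a, rep(1, n), Z, Z)
  e2 <- dtcox:::ipw_engine(f$T, f$X, f$a, rep(2, n), Z, Z)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-9)
  expect_equal(2 * e1$U1, e2$U1, tolerance = 1e-9)

  const <- cbind(z = rep(1, n))
  expect_error(dtcox:::ipw_engine(f$T, const, f$a, rep(1, n), Z, Z),
               "constant covariate")
})

test_that("with no truncation and unit weights the fit reduces to classical Cox", {
  skip_if_not_installed("survival")
  set.seed(17)
  n <- 80
  X <- data.frame(x1 = rbinom(n, 1, 0.5), x2 = runif(n))
  Tt <- rexp(n, exp(X$x1 + X$x2))
  s <- dt_sample(Tt, rep(-1, n), rep(max(Tt) + 1, n), X = X)
  fit <- dtcox(dtrunc(T, U, V) ~ x1 + x2, data = s, weight = "unit")
  ref <- survival::coxph(survival::Surv(Tt) ~ x1 + x2, data = X,
                         ties = "breslow", robust = TRUE)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(vcov(fit, "naive")), unname(ref$var), tolerance = 1e-6)
  # NPMLE-variability corrections vanish without truncation
  expect_lt(max(abs(residuals(fit, "weights"))), 1e-8)
  expect_lt(max(abs(residuals(fit, "misspec"))), 1e-8)

  # Breslow baseline agrees with the reference implementation
  bh <- survival::basehaz(survival::coxph(survival::Surv(Tt) ~ x1 + x2,
                                          data = X, ties = "breslow"),
                          centered = FALSE)
  bl <- dt_baseline(fit)
  expect_equal(bl$cumhaz, bh$hazard[match(bl$time, bh$time)],
               tolerance = 1e-8)
})

test_that("the score vanishes at the fit and the baseline hazard is a step CDF-like function", {
  s <- dt_generate(dt_sim_design(n = 120), seed = 23)
  fit <- dtcox(dtrunc(T, U, V) ~ x1 + x2, data = s)
  expect_lt(max(abs(fit$score)), 1e-8)
  for (ty in c("naive", "adj", "robust")) {
    V <- vcov(fit, ty)
    expect_equal(V, t(V), tolerance = 1e-10)
    expect_true(all(eigen(V, only.values = TRUE)$values > -1e-12))
  }
  bl <- dt_baseline(fit)
  expect_true(all(diff(bl$cumhaz) >= 0))
  expect_equal(dt_baseline(fit, times = min(s$T) - 0.01)$cumhaz, 0)
  expect_warning(dt_baseline(fit, times = max(s$T) + 1), "flat beyond")
  expect_true(all(bl$lower <= bl$surv + 1e-12 & bl$surv <= bl$upper + 1e-12))

  # events with zero weight stay in risk sets: the largest event time has
  # w = 0 under survival weights yet the fit uses all n subjects
  expect_equal(fit$n, 120L)
})

test_that("residual blocks decompose the coefficient influence as stated", {
  s <- dt_generate(dt_sim_design(n = 90), seed = 29)
  fit <- dtcox(dtrunc(T, U, V) ~ x1 + x2, data = s, weight = "survival")
  U1 <- residuals(fit, "score"); U2 <- residuals(fit, "weights")
  U3 <- residuals(fit, "misspec")
  Usum <- U1 + U2 + U3
  V <- solve(fit$info) %*% crossprod(Usum) %*% t(solve(fit$info))
  expect_equal(unname(V), unname(vcov(fit, "robust")), tolerance = 1e-10)
  # U2 is the L-weighted average of the score residuals
  np <- fit$npmle; infl <- fit$influence
  inv <- order(np$sort_index)
  U2_direct <- (crossprod(infl$L, np$a * fit$engine$U1) / np$n)[inv, ]
  expect_equal(unname(U2), unname(U2_direct), tolerance = 1e-12)
})

test_that("misspecification residuals shrink with n under the correct model", {
  u3_norm <- function(n, seed) {
    fit <- dtcox(dtrunc(T, U, V) ~ x1 + x2,
                 data = dt_generate(dt_sim_design(n = n), seed = seed))
    mean(sqrt(rowSums(residuals(fit, "misspec")^2)))
  }
  small <- mean(vapply(1:3, function(k) u3_norm(100, 30 + k), numeric(1)))
  large <- mean(vapply(1:3, function(k) u3_norm(400, 40 + k), numeric(1)))
  expect_lt(large, small)
})

test_that("predict and summary expose the fitted model", {
  s <- dt_generate(dt_sim_design(n = 60), seed = 41)
  fit <- dtcox(dtrunc(T, U, V) ~ x1 + x2, data = s)
  lp <- predict(fit, newdata = s)
  expect_equal(lp, drop(as.matrix(s[, c("x1", "x2")]) %*% coef(fit)),
               ignore_attr = TRUE)
  expect_equal(predict(fit, newdata = s, type = "risk"), exp(lp),
               ignore_attr = TRUE)
  sm <- summary(fit)
  expect_equal(unname(sm$table[, "coef"]), unname(coef(fit)))
  expect_output(print(sm), "IPW Cox")
})
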
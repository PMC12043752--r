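test_that("modified at-risk process evaluates its closed form and guards its domain", {
  expect_equal(dt_modified_at_risk(1, c(0, 0), c(1, 1), 0), 1)
  expect_equal(dt_modified_at_risk(0, 0, 5, 0.5), 1)      # 0.5/0.5 added
  expect_equal(dt_modified_at_risk(1, c(1, 2), c(0.3, 0.1), 0.2),
               1 + 0.2^exp(0.5) / (1 - 0.2^exp(0.5)))
  expect_error(dt_modified_at_risk(1, 0, 0, 1), "\\[0, 1\\)")
  expect_error(dt_modified_at_risk(1, -40, 1, 0.9), "underflow")
})

test_that("imputed at-risk expectation is proportional to the conditional baseline survival", {
  # positivity-violation-only draw: T restricted to [L, R], no random
  # truncation, single binary covariate
  S0 <- function(t) 1 - pbeta((t - 0.1) / 0.4, 2, 1.5)
  L <- 0.2; R <- 0.35
  p_true <- S0(R) / S0(L)
  set.seed(50)
  n <- 40000
  x <- rbinom(n, 1, 0.5)
  e <- exp(x)
  u <- runif(n)
  Sv <- S0(R)^e + u * (S0(L)^e - S0(R)^e)
  Tt <- 0.1 + 0.4 * qbeta(1 - Sv^(1 / e), 2, 1.5)
  tg <- seq(0.22, 0.33, length.out = 6)
  for (xv in 0:1) {
    g <- p_true^exp(xv) / (1 - p_true^exp(xv))
    Ey <- vapply(tg, function(t0) mean(Tt[x == xv] >= t0) + g, numeric(1))
    ratio <- Ey / S0(tg)^exp(xv)
    expect_lt(diff(range(ratio)) / mean(ratio), 0.05)
  }
})

test_that("p = 0 reduces exactly to the base fit and the derivative is exact", {
  s <- dt_generate(dt_sim_design(n = 150, positivity = TRUE), seed = 8)
  fit <- dtcox(dtrunc(T, U, V) ~ x1 + x2, data = s)
  sens <- dtcox_sensitivity(fit, p_grid = c(0, 0.2, 0.4))
  expect_identical(unname(sens$coef[1, ]), unname(coef(fit)))
  expect_identical(unname(sens$se[1, ]),
                   unname(sqrt(diag(vcov(fit, "robust")))))

  # analytic Newton derivative vs central differences of the modified score
  np <- fit$npmle; infl <- fit$influence; wt <- fit$weight
  p <- 0.3
  eng <- dtcox:::ipw_engine(np$T, np$X, np$a, wt$w, wt$Lw, infl$L, p = p)
  score_at <- function(b) {
    n <- np$n; X <- np$X
    e <- drop(exp(X %*% b)); cv <- e / np$a
    q <- p^e; g <- q / (1 - q)
    tf <- dtcox:::tie_first(np$T)
    S0 <- dtcox:::rev_cumsum(cv)[tf] / n + sum(cv * g) / n
    S1 <- dtcox:::rev_cumsum_mat(cv * X)[tf, ] / n
    S1 <- sweep(S1, 2, colSums(cv * g * X) / n, "+")
    colSums((wt$w / np$a) * (X - S1 / S0))
  }
  eps <- 1e-6
  for (j in 1:2) {
    b1 <- eng$beta; b2 <- eng$beta
    b1[j] <- b1[j] + eps; b2[j] <- b2[j] - eps
    num <- -(score_at(b1) - score_at(b2)) / (2 * eps)
    expect_equal(eng$info[, j], num, tolerance = 1e-4)
  }
})

test_that("the estimate is increasing in the assumed truncated mass", {
  s <- dt_generate(dt_sim_design(n = 300, positivity = TRUE), seed = 19)
  fit <- dtcox(dtrunc(T, U, V) ~ x1 + x2, data = s)
  sens <- dtcox_sensitivity(fit, p_grid = seq(0, 0.6, by = 0.1))
  b <- sens$coef[!sens$failed, 1]
  expect_true(all(diff(b) > 0))
})

test_that("sensitivity intervals are unions of the per-point intervals and nested in the cap", {
  s <- dt_generate(dt_sim_design(n = 150, positivity = TRUE), seed = 28)
  fit <- dtcox(dtrunc(T, U, V) ~ x1 + x2, data = s)
  sens <- dtcox_sensitivity(fit, p_grid = seq(0, 0.4, by = 0.1))
  si0 <- sensitivity_interval(sens, 0)
  expect_equal(si0[, "lower"], sens$lower[1, ], ignore_attr = TRUE)
  expect_equal(si0[, "upper"], sens$upper[1, ], ignore_attr = TRUE)
  si2 <- sensitivity_interval(sens, 0.2)
  si4 <- sensitivity_interval(sens, 0.4)
  expect_true(all(si4[, "lower"] <= si2[, "lower"]))
  expect_true(all(si4[, "upper"] >= si2[, "upper"]))
  expect_warning(sensitivity_interval(sens, 0.05), "p = 0 confidence interval")
  expect_error(dtcox_sensitivity(fit, p_grid = c(0, 1)), "\\[0, 1\\)")
})
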
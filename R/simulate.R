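#' Simulation designs for doubly truncated Cox data
#'
#' Defines the data-generating process used by the validation studies:
#' event times follow a Cox model whose baseline event-time law is a
#' shifted, scaled beta distribution (default `0.1 + 0.4 * Beta(2, 1.5)`,
#' support `[0.1, 0.5]`), covariates are an independent Bernoulli(0.5)
#' and Uniform(0, 1) pair with true coefficients `(1, 1)`, and the
#' truncation window is drawn independently of everything else.  Two
#' window families are built in:
#'
#' * `positivity = FALSE` (the main design): `U = 0.5 * Beta(1, 3)` and
#'   `V = U + Beta(2, 10) + 0.1`, which truncates about 36% of subjects
#'   overall while keeping the sampling probability positive everywhere;
#' * `positivity = TRUE`: `U ~ Uniform(0.18, 0.22)` and
#'   `V = U + Uniform(0.05, 0.09)`, a narrow window strictly inside the
#'   event support, so events are observable only on `[L, R] =
#'   [0.18, 0.31]` -- a genuine positivity violation.  The baseline law
#'   here is `0.1 + 0.4 * Beta(1.5, 2)`, which puts true truncated
#'   baseline mass `S0(R)/S0(L) = 0.434` (about 4/9) outside the
#'   observable range; the uniform covariate is centred so the baseline
#'   refers to a central covariate value.
#'
#' Optionally a fraction of the highest-risk subjects is contaminated:
#' among subjects with linear predictor above a cutoff `c`, a
#' Bernoulli(0.2) selection replaces the linear predictor by a standard
#' normal draw before the event time is generated, so the contaminated
#' subjects follow a different model with typically longer survival.
#' The cutoff is calibrated (by [dt_calibrate_cutoff()]) so the overall
#' contamination probability matches `contamination_prob`.
#'
#' @param n target observed (post-truncation) sample size.
#' @param beta0 true coefficient vector for `(x1, x2)`.
#' @param contamination_prob overall contamination probability (0
#'   disables contamination).
#' @param positivity use the narrow-window positivity-violation design.
#' @param baseline list with `shift`, `scale`, `shape1`, `shape2` of the
#'   baseline event-time law `shift + scale * Beta(shape1, shape2)`.
#' @param select_prob Bernoulli selection rate among cutoff exceedances.
#' @param cutoff contamination cutoff; calibrated automatically when
#'   `NULL` and `contamination_prob > 0`.
#' @return A list of class `"dt_sim_design"`.
#' @export
dt_sim_design <- function(n = 500, beta0 = c(1, 1),
                          contamination_prob = 0, positivity = FALSE,
                          baseline = NULL,
                          select_prob = 0.2, cutoff = NULL) {
  if (n < 2) stop("n >= 2 required")
  if (is.null(baseline))
    baseline <- if (positivity)
      list(shift = 0.1, scale = 0.4, shape1 = 1.5, shape2 = 2)
    else
      list(shift = 0.1, scale = 0.4, shape1 = 2, shape2 = 1.5)
  if (contamination_prob < 0 || contamination_prob >= 1)
    stop("contamination_prob must lie in [0, 1)")
  d <- structure(list(n = as.integer(n), beta0 = beta0,
                      contamination_prob = contamination_prob,
                      positivity = positivity, baseline = baseline,
                      select_prob = select_prob, cutoff = cutoff),
                 class = "dt_sim_design")
  if (contamination_prob > 0 && is.null(cutoff))
    d$cutoff <- dt_calibrate_cutoff(d, contamination_prob)
  d
}

#' @export
print.dt_sim_design <- function(x, ...) {
  cat(sprintf("Doubly truncated Cox simulation design (n = %d)\n", x$n))
  cat(sprintf("  beta0 = (%s), %s windows, contamination %.3g\n",
              paste(x$beta0, collapse = ", "),
              if (x$positivity) "narrow (positivity-violating)" else "wide",
              x$contamination_prob))
  invisible(x)
}

# baseline survival / quantile helpers for the shifted scaled beta law
baseline_survival <- function(t, bl) {
  1 - stats::pbeta((t - bl$shift) / bl$scale, bl$shape1, bl$shape2)
}

baseline_quantile <- function(pr, bl) {
  bl$shift + bl$scale * stats::qbeta(pr, bl$shape1, bl$shape2)
}

draw_covariates <- function(design, m) {
  x1 <- stats::rbinom(m, 1, 0.5)
  x2 <- stats::runif(m)
  if (design$positivity) x2 <- x2 - 0.5
  cbind(x1 = x1, x2 = x2)
}

draw_pre_truncation <- function(design, m) {
  X <- draw_covariates(design, m)
  lp <- drop(X %*% design$beta0)
  contaminated <- rep(FALSE, m)
  if (design$contamination_prob > 0) {
    contaminated <- lp > design$cutoff &
      stats::rbinom(m, 1, design$select_prob) == 1
    lp[contaminated] <- stats::rnorm(sum(contaminated))
  }
  u <- stats::runif(m)
  Tt <- baseline_quantile(1 - u^(1 / exp(lp)), design$baseline)
  if (design$positivity) {
    U <- stats::runif(m, 0.18, 0.22)
    V <- U + stats::runif(m, 0.05, 0.09)
  } else {
    U <- 0.5 * stats::rbeta(m, 1, 3)
    V <- U + stats::rbeta(m, 2, 10) + 0.1
  }
  list(T = Tt, U = U, V = V, X = X, contaminated = contaminated)
}

#' Calibrate the contamination cutoff
#'
#' Chooses the cutoff `c` so that
#' `P(x' beta0 > c) * select_prob = target_prob`, i.e. the overall
#' contamination probability hits its target, via the Monte Carlo
#' quantile of the linear predictor.
#'
#' @param design a [dt_sim_design()].
#' @param target_prob desired overall contamination probability.
#' @param mc_size Monte Carlo sample size for the quantile.
#' @param seed RNG seed for the calibration draw.
#' @return The cutoff (`Inf` when `target_prob` is 0).
#' @export
dt_calibrate_cutoff <- function(design, target_prob, mc_size = 2e5,
                                seed = 20260930L) {
  if (target_prob == 0) return(Inf)
  pex <- target_prob / design$select_prob
  if (pex <= 0 || pex >= 1)
    stop(sprintf("target contamination %.3g not attainable with selection rate %.3g (need exceedance probability in (0, 1))",
                 target_prob, design$select_prob))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lp <- drop(draw_covariates(design, mc_size) %*% design$beta0)
  stats::quantile(lp, 1 - pex, names = FALSE)
}

#' Generate a doubly truncated sample from a simulation design
#'
#' Draws pre-truncation subjects (covariates, optional contamination,
#' event time by inverse transform from the conditional survival
#' function, truncation window) and keeps those with `U <= T <= V` until
#' the target sample size is reached.  Attributes record the rejection
#' bookkeeping: total pre-truncation draws, left/right truncation
#' fractions, and the realised contamination fraction among kept
#' subjects.
#'
#' @param design a [dt_sim_design()].
#' @param seed RNG seed.
#' @return A [dt_sample()] with covariates `x1`, `x2` and attributes
#'   `n_total`, `rate_left`, `rate_right`, `rate_overall`,
#'   `contamination_rate`.
#' @export
dt_generate <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n
  keep <- list()
  tot <- left <- right <- 0L
  contam_kept <- 0L
  got <- 0L
  batch <- max(2000L, 2L * n)
  probe <- TRUE
  while (got < n) {
    d <- draw_pre_truncation(design, batch)
    tot <- tot + batch
    is_left <- d$T < d$U
    is_right <- d$T > d$V
    left <- left + sum(is_left)
    right <- right + sum(is_right)
    ok <- which(!is_left & !is_right)
    if (probe && length(ok) / batch < 1e-4)
      stop("degenerate design: keep probability below 1e-4")
    probe <- FALSE
    take <- utils::head(ok, n - got)
    keep[[length(keep) + 1L]] <-
      data.frame(T = d$T[take], U = d$U[take], V = d$V[take],
                 x1 = d$X[take, 1L], x2 = d$X[take, 2L])
    contam_kept <- contam_kept + sum(d$contaminated[take])
    got <- got + length(take)
  }
  df <- do.call(rbind, keep)
  out <- dt_sample(df$T, df$U, df$V, X = df[c("x1", "x2")])
  attr(out, "n_total") <- tot
  attr(out, "rate_left") <- left / tot
  attr(out, "rate_right") <- right / tot
  attr(out, "rate_overall") <- (left + right) / tot
  attr(out, "contamination_rate") <- contam_kept / got
  out
}

#' Monte Carlo truncation rates of a design
#'
#' Estimates the probability that a pre-truncation subject is left-,
#' right-, or overall truncated, by direct Monte Carlo.
#'
#' @param design a [dt_sim_design()].
#' @param mc_size number of pre-truncation draws.
#' @param seed RNG seed.
#' @return Named vector `c(left, right, overall)`.
#' @export
dt_truncation_rates <- function(design, mc_size = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- draw_pre_truncation(design, mc_size)
  c(left = mean(d$T < d$U), right = mean(d$T > d$V),
    overall = mean(d$T < d$U | d$T > d$V))
}

# Fit one estimator on a generated sample using prefitted NPMLE pieces.
# kind "uw" is the unweighted maximum partial likelihood comparator.
fit_one_estimator <- function(np, infl, spec) {
  n <- np$n
  if (identical(spec, "uw")) {
    eng <- ipw_engine(np$T, np$X, rep(1, n), rep(1, n),
                      matrix(0, n, n), matrix(0, n, n), p = 0)
    se_model <- sqrt(diag(solve(eng$info)))
    return(list(beta = eng$beta,
                se = cbind(naive = se_model, adj = se_model,
                           robust = se_model)))
  }
  wt <- dt_weight(np, infl, spec)
  eng <- ipw_engine(np$T, np$X, np$a, wt$w, wt$Lw, infl$L, p = 0)
  list(beta = eng$beta,
       se = cbind(naive = sqrt(diag(eng$var_naive)),
                  adj = sqrt(diag(eng$var_adj)),
                  robust = sqrt(diag(eng$var_robust))))
}

#' Coefficient simulation study
#'
#' Repeatedly generates samples from a design and fits a list of
#' estimators (weight specifications, or the string `"uw"` for the
#' unweighted partial-likelihood comparator) to the same datasets,
#' summarising bias, mean squared error, spread, mean standard errors
#' and confidence-interval coverage for the first coefficient.
#'
#' @param design a [dt_sim_design()].
#' @param estimators named list whose elements are [dt_weight_spec()]
#'   objects or the string `"uw"`.
#' @param reps number of replications.
#' @param seed root RNG seed (per-replication child seeds are spawned
#'   from it, so results are reproducible and estimators are compared on
#'   identical datasets).
#' @param level confidence level for the coverage columns.
#' @return A data frame with one row per estimator: percent bias, MSE,
#'   empirical SD, mean naive/adj/robust SEs, and coverage of the
#'   normal-approximation intervals under each SE; attributes record the
#'   failed-replication count.
#' @export
dt_run_coefficient_experiment <- function(design, estimators, reps = 200L,
                                          seed = 1L, level = 0.95) {
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, reps)
  K <- length(estimators)
  est_names <- names(estimators)
  if (is.null(est_names))
    est_names <- vapply(estimators, function(e)
      if (identical(e, "uw")) "uw" else e$kind, character(1))
  beta1 <- array(NA_real_, c(reps, K))
  ses <- array(NA_real_, c(reps, K, 3L),
               dimnames = list(NULL, NULL, c("naive", "adj", "robust")))
  failed <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch({
      samp <- dt_generate(design, seed = child[r])
      np <- dt_npmle(samp)
      needs_infl <- !all(vapply(estimators, identical, logical(1), "uw"))
      infl <- if (needs_infl) dt_influence(np) else NULL
      lapply(estimators, function(sp) fit_one_estimator(np, infl, sp))
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    for (k in seq_len(K)) {
      beta1[r, k] <- res[[k]]$beta[1L]
      ses[r, k, ] <- res[[k]]$se[1L, ]
    }
  }
  if (failed > 0.05 * reps)
    stop(sprintf("%d of %d replications failed", failed, reps))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  b0 <- design$beta0[1L]
  out <- data.frame(estimator = est_names,
                    pct_bias = NA_real_, mse = NA_real_, sd = NA_real_,
                    se_naive = NA_real_, se_adj = NA_real_,
                    se_robust = NA_real_,
                    cover_naive = NA_real_, cover_adj = NA_real_,
                    cover_robust = NA_real_)
  for (k in seq_len(K)) {
    b <- beta1[, k]; ok <- !is.na(b)
    out$pct_bias[k] <- 100 * (mean(b[ok]) - b0) / b0
    out$mse[k] <- mean((b[ok] - b0)^2)
    out$sd[k] <- stats::sd(b[ok])
    for (v in 1:3) {
      s <- ses[, k, v]
      out[[4L + v]][k] <- mean(s[ok])
      out[[7L + v]][k] <- mean(abs(b[ok] - b0) <= zq * s[ok])
    }
  }
  attr(out, "failed") <- failed
  attr(out, "reps") <- reps
  out
}

#' Sensitivity-analysis simulation study
#'
#' Repeatedly generates samples from a (typically positivity-violating)
#' design and, for each estimator, fits the sensitivity grid of assumed
#' truncated masses, summarising the bias and spread of the estimate at
#' each grid point and the length and coverage of the sensitivity
#' interval (union of confidence intervals up to each cap).
#'
#' @inheritParams dt_run_coefficient_experiment
#' @param p_grid grid of assumed truncated masses.
#' @return A data frame in long format: estimator, assumed `p`, mean
#'   bias and SD of the estimate, mean sensitivity-interval length, and
#'   sensitivity-interval coverage of the true first coefficient for the
#'   cap `q = p`.
#' @export
dt_run_sensitivity_experiment <- function(design, estimators,
                                          p_grid = seq(0, 0.45, by = 0.05),
                                          reps = 200L, seed = 1L,
                                          level = 0.95) {
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, reps)
  p_grid <- sort(p_grid)
  m <- length(p_grid)
  K <- length(estimators)
  est_names <- names(estimators)
  if (is.null(est_names))
    est_names <- vapply(estimators, function(e) e$kind, character(1))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  b0 <- design$beta0[1L]
  est <- array(NA_real_, c(reps, K, m))
  lo <- hi <- array(NA_real_, c(reps, K, m))
  failed <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch({
      samp <- dt_generate(design, seed = child[r])
      np <- dt_npmle(samp)
      infl <- dt_influence(np)
      lapply(estimators, function(sp) {
        wt <- dt_weight(np, infl, sp)
        start <- NULL
        out <- matrix(NA_real_, m, 3L)
        for (g in seq_len(m)) {
          eng <- tryCatch(ipw_engine(np$T, np$X, np$a, wt$w, wt$Lw, infl$L,
                                     p = p_grid[g], beta0 = start),
                          error = function(e) NULL)
          if (is.null(eng)) next
          se1 <- sqrt(eng$var_robust[1L, 1L])
          out[g, ] <- c(eng$beta[1L], eng$beta[1L] - zq * se1,
                        eng$beta[1L] + zq * se1)
          start <- eng$beta
        }
        out
      })
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    for (k in seq_len(K)) {
      est[r, k, ] <- res[[k]][, 1L]
      lo[r, k, ] <- res[[k]][, 2L]
      hi[r, k, ] <- res[[k]][, 3L]
    }
  }
  if (failed > 0.05 * reps)
    stop(sprintf("%d of %d replications failed", failed, reps))
  rows <- list()
  for (k in seq_len(K)) for (g in seq_len(m)) {
    b <- est[, k, g]; ok <- !is.na(b)
    si_lo <- apply(lo[, k, seq_len(g), drop = FALSE], 1L, min)
    si_hi <- apply(hi[, k, seq_len(g), drop = FALSE], 1L, max)
    rows[[length(rows) + 1L]] <-
      data.frame(estimator = est_names[k], p = p_grid[g],
                 bias = mean(b[ok]) - b0, sd = stats::sd(b[ok]),
                 si_length = mean((si_hi - si_lo)[ok]),
                 si_coverage = mean(si_lo[ok] <= b0 & b0 <= si_hi[ok]))
  }
  out <- do.call(rbind, rows)
  attr(out, "failed") <- failed
  attr(out, "reps") <- reps
  out
}
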
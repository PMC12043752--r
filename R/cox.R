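# First index of each tie group of a sorted vector.
tie_first <- function(Tt) {
  r <- rle(Tt)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  as.integer(rep.int(starts, r$lengths))
}

rev_cumsum <- function(v) rev(cumsum(rev(v)))

rev_cumsum_mat <- function(M) {
  M <- as.matrix(M)
  apply(M[rev(seq_len(nrow(M))), , drop = FALSE], 2L, cumsum)[rev(seq_len(nrow(M))), ,
                                                              drop = FALSE]
}

# Core Newton solver for the IPW partial-likelihood score with
# time-varying weights, shared by the base fit (p = 0) and the
# positivity sensitivity analysis (p > 0).  All inputs are aligned to
# event times sorted ascending.  With p > 0 the at-risk process is
# inflated by g_i = p^{exp(x_i'b)} / (1 - p^{exp(x_i'b)}), whose
# dependence on b is included in the analytic score derivative.
ipw_engine <- function(Tt, X, a, w, Lw, L, p = 0, beta0 = NULL,
                       tol = 1e-9, max_iter = 50L) {
  n <- length(Tt)
  pd <- ncol(X)
  if (pd < 1L) stop("at least one covariate is required")
  if (any(apply(X, 2L, stats::sd) == 0))
    stop("constant covariate: the partial-likelihood information is singular")
  if (p < 0 || p >= 1) stop("assumed truncated mass p must lie in [0, 1)")
  tfirst <- tie_first(Tt)
  tlast <- tie_last(Tt)
  XX <- X[, rep(seq_len(pd), times = pd), drop = FALSE] *
        X[, rep(seq_len(pd), each = pd), drop = FALSE]
  wa <- w / a

  parts <- function(beta) {
    e <- drop(exp(X %*% beta))
    cvec <- e / a
    if (p > 0) {
      q <- p^e
      if (any(1 - q < 1e-12))
        stop(sprintf("assumed truncated mass p = %g too close to 1: modified at-risk denominator underflows", p))
      g <- q / (1 - q)
      d <- q * log(p) * e / (1 - q)^2
    } else {
      g <- numeric(n); d <- numeric(n)
    }
    S0 <- rev_cumsum(cvec)[tfirst] / n + sum(cvec * g) / n
    S1 <- rev_cumsum_mat(cvec * X)[tfirst, , drop = FALSE] / n
    G1 <- colSums(cvec * g * X) / n
    S1 <- sweep(S1, 2L, G1, "+")
    list(e = e, cvec = cvec, g = g, d = d, S0 = S0, S1 = S1,
         xbar = S1 / S0)
  }

  score_fun <- function(pp) colSums(wa * (X - pp$xbar))

  neg_deriv <- function(beta, pp) {
    S2 <- rev_cumsum_mat(pp$cvec * XX)[tfirst, , drop = FALSE] / n
    G2 <- colSums(pp$cvec * pp$g * XX) / n
    S2 <- sweep(S2, 2L, G2, "+")
    # d S~1 / d beta = S~2 + D1 and d S~0 / d beta = S~1 + D0, where the
    # imputed-mass contribution through g is already inside S~1, S~2 and
    # only its beta-derivative (through d) is extra
    D0 <- colSums(pp$cvec * pp$d * X) / n
    D1 <- colSums(pp$cvec * pp$d * XX) / n
    termA <- matrix(colSums((wa / pp$S0) * S2), pd, pd) +
             matrix(sum(wa / pp$S0) * D1, pd, pd)
    R <- sweep(pp$S1, 2L, D0, "+") / pp$S0
    termB <- crossprod(wa * pp$xbar, R)
    termA - termB
  }

  beta <- if (is.null(beta0)) numeric(pd) else beta0
  pp <- parts(beta)
  sc <- score_fun(pp)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (max(abs(sc)) < tol) { converged <- TRUE; break }
    ND <- neg_deriv(beta, pp)
    step <- tryCatch(solve(ND, sc), error = function(e)
      stop("singular information: the design is not identifiable near the current estimate"))
    h <- 1
    accepted <- FALSE
    for (k in 1:25) {
      beta_new <- beta + h * step
      pp_new <- tryCatch(parts(beta_new), error = function(e) NULL)
      if (!is.null(pp_new)) {
        sc_new <- score_fun(pp_new)
        if (max(abs(sc_new)) < max(abs(sc)) || h <= 1e-4) {
          accepted <- TRUE; break
        }
      }
      h <- h / 2
    }
    if (!accepted)
      stop(sprintf("IPW Newton iteration stalled (|score| = %.3g); last estimate: %s",
                   max(abs(sc)), paste(signif(beta, 6), collapse = ", ")))
    beta <- beta_new; pp <- pp_new; sc <- sc_new
  }
  if (max(abs(sc)) < tol) converged <- TRUE
  if (!converged)
    stop(sprintf("Newton iteration did not converge in %d steps (|score| = %.3g); last estimate: %s",
                 it, max(abs(sc)), paste(signif(beta, 6), collapse = ", ")))

  # fitted hazard increments and residual blocks
  ND <- neg_deriv(beta, pp)
  dLam <- (1 / a) / (n * pp$S0)                # per-event jump of Lambda0
  A1 <- cumsum(w * dLam)[tlast]
  B1 <- row_cumsum(w * dLam * pp$xbar)[tlast, , drop = FALSE]
  A1tot <- sum(w * dLam)
  B1tot <- colSums(w * dLam * pp$xbar)
  U1 <- wa * (X - pp$xbar) -
        (pp$e / a) * (X * (A1 + pp$g * A1tot) -
                      (B1 + outer(pp$g, B1tot)))
  U2 <- crossprod(L, a * U1) / n
  U3 <- crossprod(Lw, (1 / a) * (X - pp$xbar)) / n
  NDi <- solve(ND)
  sandwich <- function(U) NDi %*% crossprod(U) %*% t(NDi)
  list(beta = beta, score = sc, info = ND, iterations = it,
       converged = converged, p = p,
       U1 = U1, U2 = U2, U3 = U3,
       var_naive = sandwich(U1),
       var_adj = sandwich(U1 + U2),
       var_robust = sandwich(U1 + U2 + U3),
       S0 = pp$S0, xbar = pp$xbar, e = pp$e, g = pp$g, dLam = dLam,
       cumhaz = cumsum(dLam)[tlast])
}

#' Doubly truncated survival response
#'
#' Packages the event time and its truncation window as the left-hand
#' side of a [dtcox()] model formula.
#'
#' @param time event time.
#' @param left left truncation time (study entry).
#' @param right right truncation time (study end).
#' @return A numeric matrix of class `"dtrunc"` with columns
#'   `time`, `left`, `right`.
#' @export
dtrunc <- function(time, left, right) {
  m <- cbind(time = time, left = left, right = right)
  class(m) <- c("dtrunc", class(m))
  m
}

#' Robust IPW Cox regression for doubly truncated data
#'
#' Fits a Cox proportional hazards model to doubly truncated event times
#' by inverse probability weighting, where the weights `1/a(T_i)` come
#' from the NPMLE of the selection probabilities and an optional
#' time-varying weight `w(t)` multiplies each event's score contribution
#' (see [dt_weight_spec()]; the default survival-function weight
#' `w(t) = 1 - F(t)` is robust to influential late events).  The
#' estimate solves the weighted partial-likelihood score
#' \deqn{\sum_i w(T_i) a(T_i)^{-1} [x_i - \bar x_a(T_i, \beta)] = 0}
#' by Newton--Raphson with step-halving, where the risk-set average
#' \eqn{\bar x_a} inverse-probability-weights every subject at risk.
#'
#' Three closed-form sandwich variance estimates are returned: `naive`
#' (score residuals only, ignoring that the weights were estimated),
#' `adj` (adding the influence of the estimated inverse weights), and
#' `robust` (further adding the influence of the estimated weight
#' function, consistent under model misspecification; the headline
#' estimate).  An IPW Breslow baseline cumulative hazard with its own
#' influence-function decomposition is also computed; see
#' [dt_baseline()].
#'
#' @param formula a model formula with a [dtrunc()] response, e.g.
#'   `dtrunc(T, U, V) ~ x1 + x2`.
#' @param data a data frame (for example a [dt_sample()]).
#' @param weight a [dt_weight_spec()] or one of its kind strings.
#' @param r,s Fleming--Harrington exponents when `weight` is a string of
#'   an `fh` kind.
#' @param npmle_tol,npmle_max_iter EM control for the NPMLE of the
#'   weights.
#' @param tol convergence tolerance on the score sup-norm.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `"dtcox"`; see [summary.dtcox()],
#'   [coef.dtcox()], [vcov.dtcox()], [residuals.dtcox()],
#'   [dt_baseline()], [dtcox_sensitivity()].
#' @export
#' @examples
#' s <- dt_generate(dt_sim_design(n = 150), seed = 7)
#' fit <- dtcox(dtrunc(T, U, V) ~ x1 + x2, data = s)
#' summary(fit)
dtcox <- function(formula, data, weight = "survival", r = 0, s = 1,
                  npmle_tol = 1e-9, npmle_max_iter = 10000L,
                  tol = 1e-9, max_iter = 50L) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "dtrunc"))
    stop("the response must be constructed with dtrunc(time, left, right)")
  tm <- stats::terms(formula, data = data)
  X <- stats::model.matrix(tm, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (is.character(weight)) weight <- dt_weight_spec(weight, r = r, s = s)
  samp <- dt_sample(y[, "time"], y[, "left"], y[, "right"],
                    X = as.data.frame(X))
  np <- dt_npmle(samp, tol = npmle_tol, max_iter = npmle_max_iter)
  infl <- dt_influence(np)
  wt <- dt_weight(np, infl, weight)
  eng <- ipw_engine(np$T, np$X, np$a, wt$w, wt$Lw, infl$L,
                    p = 0, tol = tol, max_iter = max_iter)
  inv <- order(np$sort_index)   # sorted position of each original row
  beta <- drop(eng$beta)
  names(beta) <- colnames(X)
  dimnames(eng$var_naive) <- dimnames(eng$var_adj) <-
    dimnames(eng$var_robust) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta,
                 var = list(naive = eng$var_naive, adj = eng$var_adj,
                            robust = eng$var_robust),
                 score = eng$score, info = eng$info,
                 iterations = eng$iterations, converged = eng$converged,
                 residual_blocks = list(U1 = eng$U1[inv, , drop = FALSE],
                                        U2 = eng$U2[inv, , drop = FALSE],
                                        U3 = eng$U3[inv, , drop = FALSE]),
                 baseline_times = np$T, baseline_cumhaz = eng$cumhaz,
                 npmle = np, influence = infl, weight = wt,
                 engine = eng, terms = tm, call = cl,
                 n = np$n, p = ncol(X)),
            class = "dtcox")
}

#' @export
coef.dtcox <- function(object, ...) object$coefficients

#' Variance estimate of a fitted IPW Cox model
#'
#' @param object a [dtcox()] fit.
#' @param type which sandwich estimate: `"robust"` (default), `"adj"`,
#'   or `"naive"`.
#' @param ... unused.
#' @return A `p x p` covariance matrix.
#' @export
vcov.dtcox <- function(object, type = c("robust", "adj", "naive"), ...) {
  object$var[[match.arg(type)]]
}

#' @export
print.dtcox <- function(x, ...) {
  cat("Robust IPW Cox regression for doubly truncated data\n")
  cat(sprintf("  n = %d, weight: %s\n", x$n, x$weight$label))
  print(x$coefficients)
  invisible(x)
}

#' Summary of a fitted IPW Cox model
#'
#' @param object a [dtcox()] fit.
#' @param type which standard errors drive the reported z tests and
#'   confidence intervals.
#' @param level confidence level.
#' @param ... unused.
#' @export
summary.dtcox <- function(object, type = c("robust", "adj", "naive"),
                          level = 0.95, ...) {
  type <- match.arg(type)
  b <- object$coefficients
  se <- sqrt(diag(object$var[[type]]))
  z <- b / se
  zq <- stats::qnorm(1 - (1 - level) / 2)
  tab <- cbind(coef = b, `exp(coef)` = exp(b), se = se, z = z,
               `p` = 2 * stats::pnorm(-abs(z)),
               lower = b - zq * se, upper = b + zq * se)
  out <- list(call = object$call, n = object$n, table = tab,
              se_type = type, level = level,
              weight_label = object$weight$label,
              all_se = cbind(naive = sqrt(diag(object$var$naive)),
                             adj = sqrt(diag(object$var$adj)),
                             robust = sqrt(diag(object$var$robust))))
  class(out) <- "summary.dtcox"
  out
}

#' @export
print.summary.dtcox <- function(x, ...) {
  cat("Robust IPW Cox regression for doubly truncated data\n")
  cat(sprintf("  n = %d, weight: %s, %s standard errors\n\n",
              x$n, x$weight_label, x$se_type))
  stats::printCoefmat(x$table, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nStandard errors by variance estimate:\n")
  print(round(x$all_se, 5))
  invisible(x)
}

#' Residual blocks of a fitted IPW Cox model
#'
#' @param object a [dtcox()] fit.
#' @param type `"score"` for the weighted score residuals, `"weights"`
#'   for the NPMLE-adjustment component, or `"misspec"` for the
#'   weight-function component (zero in expectation under a correctly
#'   specified model).
#' @param ... unused.
#' @return An `n x p` matrix in the original row order.
#' @export
residuals.dtcox <- function(object, type = c("score", "weights", "misspec"),
                            ...) {
  switch(match.arg(type),
         score = object$residual_blocks$U1,
         weights = object$residual_blocks$U2,
         misspec = object$residual_blocks$U3)
}

#' @export
predict.dtcox <- function(object, newdata = NULL,
                          type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$npmle$X[order(object$npmle$sort_index), , drop = FALSE]
  } else {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  }
  lp <- drop(X %*% object$coefficients)
  if (type == "risk") exp(lp) else lp
}

#' IPW Breslow baseline hazard with influence-function intervals
#'
#' Evaluates the inverse probability weighted Breslow estimator of the
#' cumulative baseline hazard at the fitted coefficients, together with
#' its influence-function decomposition into a coefficient part, a
#' weight-estimation part, and a martingale part, and the implied
#' pointwise variance.  Beyond the largest event time the hazard is flat
#' and a warning is issued (the asymptotics hold strictly inside the
#' event-time support).
#'
#' @param object a [dtcox()] fit.
#' @param times evaluation times; defaults to the sorted event times.
#' @param conf_type transformation for the survival confidence interval,
#'   `"log"` (on the cumulative hazard) or `"loglog"`.
#' @param level confidence level.
#' @return A data frame with columns `time`, `cumhaz`, `surv`, `se`
#'   (of the cumulative hazard), `lower`, `upper` (for the baseline
#'   survival curve).
#' @export
dt_baseline <- function(object, times = NULL,
                        conf_type = c("log", "loglog"), level = 0.95) {
  conf_type <- match.arg(conf_type)
  np <- object$npmle; eng <- object$engine; infl <- object$influence
  n <- np$n
  Tt <- np$T
  if (is.null(times)) times <- unique(Tt)
  if (any(times > max(Tt)))
    warning("baseline hazard is flat beyond the largest event time")
  tlast <- tie_last(Tt)
  cum <- cumsum(eng$dLam)
  idx <- findInterval(times, Tt)
  haz <- c(0, cum)[idx + 1L]

  # influence decomposition
  Lb <- -n * (eng$U1 + eng$U2 + eng$U3) %*% t(solve(eng$info))  # n x p
  cumx <- row_cumsum(eng$dLam * eng$xbar)                        # n x p
  cumx_t <- rbind(0, cumx)[idx + 1L, , drop = FALSE]
  L1 <- Lb %*% t(cumx_t)                                         # n x m
  c2 <- cumsum(eng$dLam / eng$S0)
  # L3_i(t) = a_i^{-1} [ 1(T_i <= t)/S0(T_i) - e_i * c2(min(t, T_i)) ]
  m <- length(times)
  L3 <- matrix(0, n, m)
  inv_a <- 1 / np$a
  s0T <- eng$S0
  for (k in seq_len(m)) {
    cap <- pmin(tlast, idx[k])
    L3[, k] <- inv_a * ((Tt <= times[k]) / s0T - eng$e * c(0, c2)[cap + 1L])
  }
  L2 <- crossprod(infl$L, np$a * L3) / n
  varh <- colSums((L1 + L2 + L3)^2) / n^2
  se <- sqrt(varh)
  surv <- exp(-haz)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  if (conf_type == "log") {
    lower <- exp(-(haz + zq * se))
    upper <- exp(-pmax(haz - zq * se, 0))
  } else {
    ok <- haz > 0
    lower <- upper <- rep(NA_real_, m)
    selog <- ifelse(ok, se / haz, NA_real_)
    lower[ok] <- exp(-haz[ok] * exp(zq * selog[ok]))
    upper[ok] <- exp(-haz[ok] * exp(-zq * selog[ok]))
    lower[!ok] <- surv[!ok]; upper[!ok] <- surv[!ok]
  }
  data.frame(time = times, cumhaz = haz, surv = surv, se = se,
             lower = lower, upper = upper)
}

#' @export
plot.dtcox <- function(x, conf_type = "log", ...) {
  bl <- dt_baseline(x, conf_type = conf_type)
  graphics::plot(bl$time, bl$surv, type = "s", ylim = c(0, 1),
                 xlab = "time", ylab = expression(S[0](t)),
                 main = "IPW baseline survival", ...)
  graphics::lines(bl$time, bl$lower, type = "s", lty = 2)
  graphics::lines(bl$time, bl$upper, type = "s", lty = 2)
  invisible(x)
}
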
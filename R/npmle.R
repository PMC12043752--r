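#' Inclusion (comparability) matrix of a doubly truncated sample
#'
#' Entry `(i, j)` is 1 when the i-th event time falls inside the j-th
#' subject's truncation window, i.e. `U[j] <= T[i] <= V[j]`.  The diagonal
#' is always 1 because each subject was observed inside its own window.
#' This matrix defines both the nonparametric likelihood and the
#' identifiability graph of the NPMLE.
#'
#' @param sample a [dt_sample()] (or any data frame with columns `T`, `U`,
#'   `V`).
#' @return An `n x n` 0/1 matrix.
#' @export
dt_inclusion_matrix <- function(sample) {
  Tt <- sample$T
  J <- outer(Tt, sample$U, ">=") & outer(Tt, sample$V, "<=")
  storage.mode(J) <- "double"
  J
}

#' Check the strong-connectedness (identifiability) condition
#'
#' The NPMLE of the event-time distribution under double truncation is
#' uniquely defined when the directed graph with an edge from i to j
#' whenever `T[j]` lies in `[U[i], V[i]]` is strongly connected.  When it
#' is not, the likelihood factorises over the strongly connected
#' components and the relative masses between components are not
#' identified.
#'
#' @param J an inclusion matrix from [dt_inclusion_matrix()], or a
#'   [dt_sample()] from which one is built.
#' @return A list with elements `connected` (logical), `n_components`, and
#'   `membership` (integer component label per subject).
#' @export
dt_strong_connected <- function(J) {
  if (is.data.frame(J)) J <- dt_inclusion_matrix(J)
  # edge i -> j iff T_j is inside window i, i.e. J[j, i] == 1
  g <- igraph::graph_from_adjacency_matrix(t(J) != 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  list(connected = comp$no == 1L,
       n_components = comp$no,
       membership = as.integer(comp$membership))
}

#' NPMLE of the event-time distribution under double truncation
#'
#' Places point masses `phi[i]` at the observed event times and maximises
#' the nonparametric likelihood `prod(phi[i] / Phi[i])`, where
#' `Phi[j] = sum_i J[i, j] phi[i]` is the probability that an event drawn
#' from the estimated distribution falls inside subject j's window.  The
#' maximiser is computed by the classical EM iteration
#' `Phi = t(J) phi`, `1/phi <- J (1/Phi)`, followed by renormalisation.
#' The fitted masses determine the selection probabilities through
#' `a(T[i]) = 1 / (n phi[i])`, which are the reciprocals of the inverse
#' probability weights used by [dtcox()].
#'
#' Subjects are sorted by event time internally; `sort_index` maps sorted
#' positions back to input rows.  Ties receive separate (equal) masses so
#' that all downstream matrices stay subject-aligned.
#'
#' @param sample a [dt_sample()].
#' @param tol convergence tolerance on the maximum absolute change in
#'   `phi` between iterations.
#' @param max_iter maximum number of EM iterations.
#' @param check_connected check the identifiability condition first and
#'   fail if it does not hold (recommended).
#' @return An object of class `"dt_npmle"` with elements `phi`, `Phi`,
#'   `J`, `a` (selection probabilities at the sorted event times), `T`,
#'   `U`, `V` (sorted), `X` (covariates, sorted), `sort_index`,
#'   `iterations`, `converged`, `max_delta` and `loglik`.
#' @references The EM iteration and likelihood are the standard
#'   nonparametric treatment of doubly truncated data originating with the
#'   Efron--Petrosian estimator.
#' @export
#' @examples
#' d <- dt_sim_design(n = 80)
#' s <- dt_generate(d, seed = 1)
#' f <- dt_npmle(s)
#' f
dt_npmle <- function(sample, tol = 1e-9, max_iter = 10000L,
                     check_connected = TRUE) {
  n <- nrow(sample)
  if (is.null(n) || n < 2) stop("need at least two subjects")
  ord <- order(sample$T)
  Tt <- sample$T[ord]; U <- sample$U[ord]; V <- sample$V[ord]
  X <- sample_covariates(sample)
  X <- X[ord, , drop = FALSE]
  s <- data.frame(T = Tt, U = U, V = V)
  J <- dt_inclusion_matrix(s)
  if (check_connected) {
    sc <- dt_strong_connected(J)
    if (!sc$connected)
      stop(sprintf(paste0("NPMLE not identifiable: the inclusion graph has %d ",
                          "strongly connected components (strong connectedness ",
                          "fails)"), sc$n_components))
  }
  phi <- rep(1 / n, n)
  converged <- FALSE
  delta <- NA_real_
  it <- 0L
  repeat {
    it <- it + 1L
    Phi <- drop(crossprod(J, phi))
    inv_new <- drop(J %*% (1 / Phi))
    phi_new <- 1 / inv_new
    phi_new <- phi_new / sum(phi_new)
    delta <- max(abs(phi_new - phi))
    phi <- phi_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  Phi <- drop(crossprod(J, phi))
  a <- drop(J %*% (1 / Phi)) / n
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations (max |dphi| = %.3g)",
                    it, delta))
  structure(list(phi = phi, Phi = Phi, J = J, a = a,
                 T = Tt, U = U, V = V, X = X,
                 sort_index = ord, n = n,
                 iterations = it, converged = converged, max_delta = delta,
                 loglik = sum(log(phi) - log(Phi))),
            class = "dt_npmle")
}

#' @export
print.dt_npmle <- function(x, ...) {
  cat(sprintf("NPMLE for doubly truncated data (n = %d)\n", x$n))
  cat(sprintf("  EM iterations: %d (%sconverged, max |dphi| = %.2g)\n",
              x$iterations, if (x$converged) "" else "NOT ", x$max_delta))
  cat(sprintf("  log nonparametric likelihood: %.6f\n", x$loglik))
  cat(sprintf("  selection probabilities a(T) in [%.4g, %.4g]\n",
              min(x$a), max(x$a)))
  invisible(x)
}

#' @export
summary.dt_npmle <- function(object, ...) {
  qs <- dt_cdf_quantile(object, c(0.25, 0.5, 0.75))
  out <- list(n = object$n, iterations = object$iterations,
              converged = object$converged,
              quartiles = qs, a_range = range(object$a),
              alpha = dt_alpha(object))
  class(out) <- "summary.dt_npmle"
  out
}

#' @export
print.summary.dt_npmle <- function(x, ...) {
  cat(sprintf("NPMLE summary (n = %d)\n", x$n))
  cat(sprintf("  estimated quartiles of the event-time distribution: %.4g / %.4g / %.4g\n",
              x$quartiles[1], x$quartiles[2], x$quartiles[3]))
  cat(sprintf("  selection probability range: [%.4g, %.4g]\n",
              x$a_range[1], x$a_range[2]))
  cat(sprintf("  estimated overall sampling probability alpha: %.4g\n", x$alpha))
  invisible(x)
}

#' Event-time CDF of a fitted NPMLE
#'
#' Right-continuous step function `F(t) = sum_i 1(T[i] <= t) phi[i]`,
#' evaluated at arbitrary times.
#'
#' @param fit a [dt_npmle()] fit.
#' @param t numeric vector of evaluation times.
#' @return Numeric vector of CDF values in `[0, 1]`.
#' @export
dt_cdf <- function(fit, t) {
  idx <- findInterval(t, fit$T)          # number of sorted T <= t
  cs <- c(0, cumsum(fit$phi))
  cs[idx + 1L]
}

# Quantiles (smallest t with F(t) >= p) of the fitted step CDF.
dt_cdf_quantile <- function(fit, p) {
  cs <- cumsum(fit$phi)
  vapply(p, function(pp) fit$T[which(cs >= pp - 1e-12)[1L]], numeric(1))
}

#' Selection probability of a fitted NPMLE
#'
#' The normalised probability `a(t)` that a subject with event time `t`
#' would be sampled, estimated by
#' `a(t) = n^-1 sum_j 1(U[j] <= t <= V[j]) / Phi[j]`.  At the observed
#' event times this equals `1 / (n phi[i])`.  The closed-interval
#' indicator makes `a` right-continuous at left truncation times and
#' left-continuous at right truncation times.
#'
#' @param fit a [dt_npmle()] fit.
#' @param t numeric vector of evaluation times.
#' @param warn warn when `a(t) = 0` (t outside every observed window).
#' @return Numeric vector of selection probabilities.
#' @export
dt_selection_probability <- function(fit, t, warn = TRUE) {
  ind <- outer(t, fit$U, ">=") & outer(t, fit$V, "<=")
  storage.mode(ind) <- "double"
  out <- drop(ind %*% (1 / fit$Phi)) / fit$n
  if (warn && any(out == 0))
    warning("a(t) = 0 at some queried times (outside all observed truncation windows)")
  out
}

#' Estimated overall sampling probability
#'
#' The probability `alpha` that a pre-truncation subject is observed,
#' estimated from the NPMLE of the truncation-time distribution, which
#' places mass proportional to `1 / Phi[j]` on the observed window
#' `(U[j], V[j])`.  This gives `alpha = n / sum_j (1 / Phi[j])` and the
#' unnormalised selection probability `pi(t) = alpha * a(t)`.
#'
#' @param fit a [dt_npmle()] fit.
#' @return A single probability.
#' @export
dt_alpha <- function(fit) {
  fit$n / sum(1 / fit$Phi)
}

#' Unnormalised selection probability pi(t)
#'
#' `pi(t) = P(U <= t <= V)` under the estimated truncation-time
#' distribution; equals `alpha * a(t)`.
#'
#' @inheritParams dt_selection_probability
#' @return Numeric vector of probabilities.
#' @export
dt_pi <- function(fit, t) {
  dt_alpha(fit) * dt_selection_probability(fit, t, warn = FALSE)
}

#' @export
#' @rdname dt_npmle
#' @param object,... method arguments; `predict.dt_npmle` evaluates the
#'   fitted CDF or selection probability at `times`.
#' @param times evaluation times for `predict`.
#' @param type `"cdf"`, `"selection"` (normalised `a(t)`) or `"pi"`.
predict.dt_npmle <- function(object, times, type = c("cdf", "selection", "pi"),
                             ...) {
  type <- match.arg(type)
  switch(type,
         cdf = dt_cdf(object, times),
         selection = dt_selection_probability(object, times),
         pi = dt_pi(object, times))
}

#' @export
plot.dt_npmle <- function(x, what = c("cdf", "selection"), ...) {
  what <- match.arg(what)
  if (what == "cdf") {
    graphics::plot(stats::stepfun(x$T, c(0, cumsum(x$phi))),
                   do.points = FALSE, xlab = "time", ylab = "F(t)",
                   main = "NPMLE of the event-time CDF", ...)
  } else {
    tt <- sort(unique(c(x$T, x$U, x$V)))
    graphics::plot(tt, dt_selection_probability(x, tt, warn = FALSE),
                   type = "s", xlab = "time", ylab = "a(t)",
                   main = "Estimated selection probability", ...)
  }
  invisible(x)
}
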
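#' Conditional Kendall's tau for doubly truncated data
#'
#' Rank correlation between event and left-truncation times over
#' "comparable" pairs: pairs whose two event times both lie inside the
#' intersection of the two truncation windows, so that swapping the
#' windows between the subjects would still satisfy the sampling
#' constraint.  Under quasi-independent truncation the expected
#' correlation is zero.
#'
#' Inference is by a constrained permutation null: window assignments
#' are shuffled by a random-transposition Markov chain that only accepts
#' swaps keeping every event inside its assigned window (the uniform
#' distribution over feasible assignments is the exact null conditional
#' on the data).  The two-sided p-value compares `|tau|` against the
#' permuted values.
#'
#' @param sample a [dt_sample()] (or a stratum thereof).
#' @param n_perm number of permutation draws.
#' @param sweeps proposed transpositions between consecutive draws,
#'   as a multiple of `n`.
#' @param seed optional RNG seed.
#' @return A list with `tau`, `n_comparable`, `p_value`, `null_sd`, and
#'   the vector of permuted statistics `null`.
#' @export
conditional_kendall_tau <- function(sample, n_perm = 1000L, sweeps = 4,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Tt <- sample$T; U <- sample$U; V <- sample$V
  n <- length(Tt)
  J <- dt_inclusion_matrix(sample)     # J[i, k] = 1(T_i in window k)
  signT <- sign(outer(Tt, Tt, "-"))
  tau_of <- function(s) {
    Jp <- J[, s, drop = FALSE]
    comp <- (Jp * t(Jp)) == 1
    diag(comp) <- FALSE
    nc <- sum(comp) / 2
    if (nc == 0) return(c(NA_real_, 0))
    su <- sign(outer(U[s], U[s], "-"))
    c(sum(signT * su * comp) / 2 / nc, nc)
  }
  obs <- tau_of(seq_len(n))
  if (obs[2] == 0)
    stop("no comparable pairs: conditional Kendall's tau is undefined")
  nprop <- ceiling(sweeps * n)
  s <- seq_len(n)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    ii <- sample.int(n, nprop, replace = TRUE)
    jj <- sample.int(n, nprop, replace = TRUE)
    for (k in seq_len(nprop)) {
      i <- ii[k]; j <- jj[k]
      if (i != j && J[i, s[j]] == 1 && J[j, s[i]] == 1) {
        tmp <- s[i]; s[i] <- s[j]; s[j] <- tmp
      }
    }
    null[b] <- tau_of(s)[1]
  }
  null <- null[!is.na(null)]
  pv <- (1 + sum(abs(null) >= abs(obs[1]) - 1e-12)) / (length(null) + 1)
  list(tau = obs[1], n_comparable = obs[2], p_value = pv,
       null_sd = stats::sd(null), null = null)
}

# pi-hat(t) on a grid plus per-subject influence rows, for one (sub)sample.
pi_with_influence <- function(fit, infl, grid) {
  n <- fit$n
  a_t <- dt_selection_probability(fit, grid, warn = FALSE)
  alpha <- dt_alpha(fit)
  a_infl <- dt_influence_at(fit, infl, grid, what = "a")
  # influence of alpha-hat = 1/m, m = mean(1/Phi):
  # empirical part (1/Phi_i - m) plus the functional part through
  # Phi_k = F(V_k) - F(U_k-), whose F-influence increments are the rows
  # of W2.
  m <- mean(1 / fit$Phi)
  psi_m <- (1 / fit$Phi - m) - colSums(infl$W2 / fit$Phi^2) / n
  alpha_infl <- -alpha^2 * psi_m
  psi <- alpha * a_infl + outer(a_t, alpha_infl)
  list(pi = alpha * a_t, psi = psi)
}

#' Nonparametric diagnostic for quasi-independent truncation
#'
#' Splits the sample into covariate strata, estimates the selection
#' probability curve `pi(t | s)` by a stratum-specific NPMLE, and
#' compares it with the pooled curve `pi(t)`.  Under quasi-independent
#' truncation the truncation-time law does not depend on the stratum, so
#' all curves estimate the same function.  The test statistic is
#' `sup over t, s of |pi(t|s) - pi(t)|`; its null distribution is
#' approximated by multiplier draws from the estimated limiting Gaussian
#' process, using the closed-form influence estimates, which also yield
#' a uniform confidence band centred at the pooled curve.  A
#' stratum-specific conditional Kendall's tau (with an aggregate
#' chi-square combination) checks quasi-independence within strata.
#'
#' @param sample a [dt_sample()].
#' @param strata a vector (factor) assigning each subject to a stratum.
#' @param n_null number of Gaussian-process draws.
#' @param n_perm permutations for the per-stratum Kendall tests (0 to
#'   skip them).
#' @param seed optional RNG seed.
#' @return An object of class `"dt_qi_test"` with the per-stratum taus
#'   and p-values, the aggregate tau p-value, the sup statistic and its
#'   p-value, the evaluation grid, the estimated curves, and the 95%
#'   band half-width.
#' @export
dt_quasi_independence_test <- function(sample, strata, n_null = 2000L,
                                       n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strata <- as.factor(strata)
  S <- nlevels(strata)
  n <- nrow(sample)
  if (S > 4)
    warning("more than 4 strata: power tends to degrade; 2-4 strata are recommended")
  sizes <- table(strata)
  if (any(sizes < 20))
    warning("strata with fewer than 20 subjects: stratum-specific NPMLEs may be unstable")
  grid <- sort(unique(c(sample$T, sample$U, sample$V)))
  grid <- grid[grid >= min(sample$T) & grid <= max(sample$T)]
  m <- length(grid)

  pooled_fit <- dt_npmle(sample)
  pooled_infl <- dt_influence(pooled_fit)
  pooled <- pi_with_influence(pooled_fit, pooled_infl, grid)

  taus <- data.frame(stratum = levels(strata), n = as.integer(sizes),
                     tau = NA_real_, p_value = NA_real_, null_sd = NA_real_)
  pi_s <- matrix(NA_real_, m, S, dimnames = list(NULL, levels(strata)))
  psi_s <- vector("list", S)
  idx_s <- vector("list", S)
  for (s in seq_len(S)) {
    rows <- which(strata == levels(strata)[s])
    idx_s[[s]] <- rows
    sub <- sample[rows, , drop = FALSE]
    fit_s <- tryCatch(dt_npmle(sub),
                      error = function(e)
                        stop(sprintf("stratum '%s': %s", levels(strata)[s],
                                     conditionMessage(e))))
    infl_s <- dt_influence(fit_s)
    ps <- pi_with_influence(fit_s, infl_s, grid)
    pi_s[, s] <- ps$pi
    psi_s[[s]] <- ps$psi
    if (n_perm > 0) {
      kt <- conditional_kendall_tau(sub, n_perm = n_perm)
      taus$tau[s] <- kt$tau
      taus$p_value[s] <- kt$p_value
      taus$null_sd[s] <- kt$null_sd
    }
  }
  agg_p <- NA_real_
  if (n_perm > 0) {
    chi <- sum((taus$tau / taus$null_sd)^2)
    agg_p <- stats::pchisq(chi, df = S, lower.tail = FALSE)
  }

  stat <- max(abs(pi_s - pooled$pi))
  # multiplier draws of the limiting process; one standard normal per
  # subject (original row id), shared between the stratum curves and the
  # pooled curve so their dependence is preserved
  Xi <- matrix(stats::rnorm(n * n_null), n, n_null)
  Dpool <- pooled$psi %*% Xi[pooled_fit$sort_index, , drop = FALSE] / n
  sups <- rep(0, n_null)
  for (s in seq_len(S)) {
    # columns of psi_s are the stratum's subjects in event-time order
    ord_sub <- idx_s[[s]][dt_npmle_order(sample[idx_s[[s]], , drop = FALSE])]
    Ds <- psi_s[[s]] %*% Xi[ord_sub, , drop = FALSE] / length(idx_s[[s]])
    sups <- pmax(sups, apply(abs(Ds - Dpool), 2L, max))
  }
  band <- stats::quantile(sups, 0.95, names = FALSE)
  structure(list(strata = levels(strata), sizes = as.integer(sizes),
                 taus = taus, aggregate_tau_p = agg_p,
                 grid = grid, pi_by_stratum = pi_s, pi_pooled = pooled$pi,
                 sup_stat = stat,
                 p_value = mean(sups >= stat - 1e-12),
                 band_halfwidth = band, n_null = n_null),
            class = "dt_qi_test")
}

# sort order of a (sub)sample by event time, matching dt_npmle's internal
# ordering
dt_npmle_order <- function(sample) order(sample$T)

#' @export
print.dt_qi_test <- function(x, ...) {
  cat("Diagnostic for quasi-independent truncation\n")
  cat(sprintf("  strata: %s (n = %s)\n", paste(x$strata, collapse = ", "),
              paste(x$sizes, collapse = ", ")))
  if (!all(is.na(x$taus$tau))) {
    cat("  conditional Kendall's tau within strata:\n")
    print(x$taus, row.names = FALSE)
    cat(sprintf("  aggregate tau p-value: %.3g\n", x$aggregate_tau_p))
  }
  cat(sprintf("  sup |pi(t|s) - pi(t)| = %.4g, p-value = %.3g (%d null draws)\n",
              x$sup_stat, x$p_value, x$n_null))
  invisible(x)
}

#' @export
plot.dt_qi_test <- function(x, ...) {
  graphics::matplot(x$grid, x$pi_by_stratum, type = "s", lty = 1,
                    col = "grey60", xlab = "time", ylab = expression(pi(t)),
                    main = "Quasi-independence diagnostic", ...)
  graphics::lines(x$grid, x$pi_pooled, type = "s", lwd = 2)
  graphics::lines(x$grid, x$pi_pooled + x$band_halfwidth, type = "s", lty = 2)
  graphics::lines(x$grid, pmax(x$pi_pooled - x$band_halfwidth, 0), type = "s",
                  lty = 2)
  invisible(x)
}

#' Tests for ignorable sampling bias
#'
#' Tests the hypothesis that the selection probability is flat,
#' `a(t) = 1` (equivalently that the truncation-corrected CDF equals
#' the empirical CDF), in which case ordinary untruncated methods are
#' valid.  Two statistics are available: `sqrt(n) sup |F - F*|`
#' comparing the NPMLE with the empirical CDF over the event times, and
#' `sqrt(n) sup |a(t) - 1|` over the merged grid of event and truncation
#' times.  Null distributions are approximated by multiplier draws of
#' the limiting Gaussian process using the closed-form influence
#' estimates.
#'
#' @param fit a [dt_npmle()] fit.
#' @param infl the matching [dt_influence()] object.
#' @param statistic `"cdf"` or `"selection"`.
#' @param n_null number of Gaussian-process draws.
#' @param seed optional RNG seed.
#' @return A list with `statistic`, `p_value`, and the draw vector
#'   `null`.
#' @export
dt_ignorable_bias_test <- function(fit, infl,
                                   statistic = c("cdf", "selection"),
                                   n_null = 2000L, seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  n <- fit$n
  if (statistic == "cdf") {
    Fhat <- cumsum(fit$phi)[infl$rep_idx]
    Fstar <- infl$rep_idx / n
    stat <- sqrt(n) * max(abs(Fhat - Fstar))
    ind <- outer(fit$T, fit$T, ">=")     # (j, i): T_i <= T_j
    storage.mode(ind) <- "double"
    Psi <- infl$calA - ind + Fhat
  } else {
    # the statistic is a sup over the event-time support; truncation
    # endpoints refine the grid but must be clipped to [min T, max T]
    grid <- sort(unique(c(fit$T, fit$U, fit$V)))
    grid <- grid[grid >= min(fit$T) & grid <= max(fit$T)]
    a_t <- dt_selection_probability(fit, grid, warn = FALSE)
    stat <- sqrt(n) * max(abs(a_t - 1))
    Psi <- dt_influence_at(fit, infl, grid, what = "a")
  }
  Xi <- matrix(stats::rnorm(n * n_null), n, n_null)
  sups <- apply(abs(Psi %*% Xi), 2L, max) / sqrt(n)
  list(statistic = stat, p_value = mean(sups >= stat - 1e-12), null = sups)
}
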
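# Internal helpers for the triangular operators used throughout the
# influence-function algebra.  With S the lower-triangular matrix of ones,
# S %*% M is a columnwise cumulative sum, S^{-1} %*% M a first difference
# down the rows, and M %*% S^{-1} a first difference across the columns
# (right-to-left).  S^{-1} is never formed explicitly.

row_cumsum <- function(M) apply(M, 2L, cumsum)

row_diff <- function(M) {
  out <- M
  if (nrow(M) > 1L) out[-1L, ] <- M[-1L, , drop = FALSE] - M[-nrow(M), , drop = FALSE]
  out
}

col_diff_right <- function(M) {
  n <- ncol(M)
  out <- M
  if (n > 1L) out[, -n] <- M[, -n, drop = FALSE] - M[, -1L, drop = FALSE]
  out
}

# Index of the last member of each tie group of a sorted vector.
tie_last <- function(Tt) {
  r <- rle(Tt)
  ends <- cumsum(r$lengths)
  as.integer(rep.int(ends, r$lengths))
}

#' Plug-in influence matrices for the NPMLE
#'
#' Computes the closed-form plug-in estimates of the influence functions
#' of the NPMLE CDF and of the selection probabilities, evaluated at the
#' observed (sorted) event times.  Entry `(j, i)` of `calA` estimates the
#' influence of data point `i` on `F(T[j])`; entry `(j, i)` of `L`
#' estimates the influence of data point `i` on `1/a(T[j])`, the inverse
#' probability weight.  These matrices are the sole ingredient of every
#' closed-form standard error in the package, replacing bootstrap
#' resampling.
#'
#' The computation solves one dense `(n-1) x (n-1)` linear system (the
#' finite-sample analogue of inverting `I - A`, where `A` is the plug-in
#' smoothing operator); its reciprocal condition number is returned so
#' near-failures of identifiability are visible.  The inverse of the
#' triangular summation matrix is applied as a difference operator rather
#' than being formed.
#'
#' @param fit a converged [dt_npmle()] fit.
#' @param complete also return the operator matrices `A` and `Atilde`
#'   and the building blocks `B`, `Iu` (tie representative indices).
#'   These are only needed for diagnostics and testing.
#' @return An object of class `"dt_influence"`: list with `H` (plug-in
#'   estimates of the primitive influence kernel), `calA`, `L`, `a_infl`
#'   (influence of `a(t)` itself), `W2` (an internal product reused when
#'   evaluating at new time points), `rcond` and, if `complete`, `A`,
#'   `Atilde`, `B`, `Iu`.
#' @export
dt_influence <- function(fit, complete = FALSE) {
  stopifnot(inherits(fit, "dt_npmle"))
  n <- fit$n
  phi <- fit$phi; Phi <- fit$Phi; J <- fit$J; Tt <- fit$T
  a <- fit$a
  rep_idx <- tie_last(Tt)

  # H[i, j] = n phi_j 1(T_j <= T_i) - n sum_k J[k, j] 1(T_k <= T_i) phi_k^2 / Phi_j
  cum <- row_cumsum(phi^2 * J)[rep_idx, , drop = FALSE]
  M1 <- outer(Tt, Tt, ">=")
  storage.mode(M1) <- "double"
  H <- n * sweep(M1, 2L, phi, "*") - n * sweep(cum, 2L, Phi, "/")

  # operator matrix A = S diag(phi^2) J diag(1/Phi^2) J^T S^{-1}
  G <- tcrossprod(sweep(J, 2L, Phi^2, "/"), J)     # J diag(1/Phi^2) J^T
  A <- col_diff_right(row_cumsum(phi^2 * G))

  # B = S diag(phi); BC has columns B[, j] - B[, n]
  Bm <- outer(seq_len(n), seq_len(n), ">=") * rep(phi, each = n)
  BC <- Bm[, -n, drop = FALSE] - Bm[, n]
  IA_BC <- BC - A %*% BC
  binv <- function(M) sweep(row_diff(M), 1L, phi, "/")
  ct <- function(M) M[-n, , drop = FALSE] - rep(M[n, ], each = n - 1L)
  inner <- ct(binv(IA_BC))
  rc <- rcond(inner)
  Z <- tryCatch(solve(inner, ct(binv(H))),
                error = function(e)
                  stop(sprintf(paste0("influence system is numerically singular ",
                                      "(rcond = %.3g); the sample is at or near an ",
                                      "identifiability failure"), rc)))
  calA <- (BC %*% Z)[rep_idx, , drop = FALSE]

  # products with Atilde = J diag(1/Phi^2) J^T S^{-1} / n, via
  # W2 = J^T S^{-1} calA so rows at arbitrary t are cheap
  W2 <- crossprod(J, row_diff(calA))
  AtC <- J %*% sweep(W2, 1L, Phi^2, "/") / n

  a_infl <- sweep(J, 2L, Phi, "/") - a - AtC
  L <- -a_infl / a^2

  out <- list(H = H, calA = calA, L = L, a_infl = a_infl, W2 = W2,
              rcond = rc, rep_idx = rep_idx, n = n)
  if (complete) {
    out$A <- A
    out$Atilde <- col_diff_right(G) / n
    out$B <- Bm
    out$Iu <- rep_idx
  }
  class(out) <- "dt_influence"
  out
}

#' @export
print.dt_influence <- function(x, ...) {
  cat(sprintf("Plug-in NPMLE influence matrices (n = %d)\n", x$n))
  cat(sprintf("  reciprocal condition number of the inner system: %.3g\n", x$rcond))
  invisible(x)
}

#' Influence estimates of the selection probability at arbitrary times
#'
#' Evaluates the plug-in influence estimates of `a(t)` (and of the
#' inverse weight `1/a(t)`) at time points other than the observed event
#' times, by recomputing the window-indicator row
#' `1(U[i] <= t <= V[i])`.  Evaluated at an observed event time the rows
#' agree exactly with those stored in [dt_influence()].
#'
#' @param fit a [dt_npmle()] fit.
#' @param infl the matching [dt_influence()] object.
#' @param t numeric vector of evaluation times.
#' @param what `"inverse"` for the influence of `1/a(t)` (the weight), or
#'   `"a"` for the influence of `a(t)` itself.
#' @return A `length(t) x n` matrix; row `j` holds the per-subject
#'   influence estimates at `t[j]`.
#' @export
dt_influence_at <- function(fit, infl, t, what = c("inverse", "a")) {
  what <- match.arg(what)
  ind <- outer(t, fit$U, ">=") & outer(t, fit$V, "<=")
  storage.mode(ind) <- "double"
  a_t <- drop(ind %*% (1 / fit$Phi)) / fit$n
  AtC <- ind %*% sweep(infl$W2, 1L, fit$Phi^2, "/") / fit$n
  a_infl <- sweep(ind, 2L, fit$Phi, "/") - a_t - AtC
  if (what == "a") return(a_infl)
  if (any(a_t == 0))
    stop("a(t) = 0 at some evaluation times; influence of 1/a(t) undefined there")
  -a_infl / a_t^2
}

#' Pointwise variance of the NPMLE CDF
#'
#' Influence-function variance estimate of `F(t)`:
#' `n^-2 sum_i infl_i(t)^2`, with the influence rows taken from the step
#' structure of `calA` (right-continuous jumps at event times).
#'
#' @inheritParams dt_influence_at
#' @return Numeric vector of variances, one per element of `t`.
#' @export
dt_cdf_variance <- function(fit, infl, t) {
  idx <- findInterval(t, fit$T)
  out <- numeric(length(t))
  nz <- idx > 0L
  if (any(nz))
    out[nz] <- rowSums(infl$calA[idx[nz], , drop = FALSE]^2) / fit$n^2
  out
}
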
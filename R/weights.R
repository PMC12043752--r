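#' Time-varying weight specifications for IPW Cox regression
#'
#' The IPW partial-likelihood score multiplies each event's contribution
#' by `w(T_i) / a(T_i)`, where `a` is the estimated selection probability
#' and `w` a time-varying weight function chosen from:
#'
#' * `"unit"`: `w(t) = 1`, the standard IPW partial likelihood;
#' * `"stabilized"`: `w(t) = a(t)`, which cancels the inverse weight in
#'   each event's own term;
#' * `"survival"`: `w(t) = 1 - F(t)`, the recommended robust choice --
#'   each event is weighted by the estimated fraction of the
#'   pre-truncation population still at risk;
#' * `"fh"`: Fleming--Harrington weights `w(t) = F(t)^r (1 - F(t))^s`;
#' * `"stabilized_survival"`, `"stabilized_fh"`: the products of
#'   `a(t)` with the survival and Fleming--Harrington weights.
#'
#' @param kind one of the six weight kinds above.
#' @param r,s nonnegative Fleming--Harrington exponents (only used by the
#'   `fh` kinds).
#' @return A list of class `"dt_weight_spec"`.
#' @export
dt_weight_spec <- function(kind = c("unit", "stabilized", "survival", "fh",
                                    "stabilized_survival", "stabilized_fh"),
                           r = 0, s = 1) {
  kind <- match.arg(kind)
  if (r < 0 || s < 0) stop("Fleming-Harrington exponents must be nonnegative")
  structure(list(kind = kind, r = r, s = s), class = "dt_weight_spec")
}

weight_label <- function(spec) {
  switch(spec$kind,
         unit = "w(t) = 1",
         stabilized = "w(t) = a(t)",
         survival = "w(t) = 1 - F(t)",
         fh = sprintf("w(t) = F(t)^%g (1-F(t))^%g", spec$r, spec$s),
         stabilized_survival = "w(t) = a(t) (1 - F(t))",
         stabilized_fh = sprintf("w(t) = a(t) F(t)^%g (1-F(t))^%g", spec$r, spec$s))
}

# derivative of F^r (1-F)^s with respect to F, with 0^x guards at the
# boundary masses (where the weight itself vanishes)
fh_deriv <- function(Fv, r, s) {
  t1 <- if (r == 0) 0 else ifelse(Fv > 0, r * Fv^(r - 1) * (1 - Fv)^s, 0)
  t2 <- if (s == 0) 0 else ifelse(Fv < 1, s * Fv^r * (1 - Fv)^(s - 1), 0)
  t1 - t2
}

#' Evaluate a time-varying weight and its influence estimates
#'
#' Evaluates the weight function at the observed (sorted) event times and
#' assembles the plug-in influence estimates of the weight function by
#' the delta method: the influence of `F` is the `calA` matrix, the
#' influence of `a` is `a_infl`, and products and powers combine by the
#' product and chain rules.  The influence block `Lw` feeds the
#' model-misspecification-robust part of the sandwich variance in
#' [dtcox()].
#'
#' @param fit a [dt_npmle()] fit.
#' @param infl the matching [dt_influence()] object.
#' @param spec a [dt_weight_spec()] (or a kind string passed to it).
#' @return An object of class `"dt_weight"` with `w` (weight at the
#'   sorted event times), `Lw` (`n x n` influence estimates, entry (j,i)
#'   the influence of datum i on `w(T[j])`), and `spec`.
#' @export
dt_weight <- function(fit, infl, spec = dt_weight_spec("survival")) {
  if (is.character(spec)) spec <- dt_weight_spec(spec)
  n <- fit$n
  Fv <- cumsum(fit$phi)[infl$rep_idx]   # F at event times, ties collapsed
  a <- fit$a
  calA <- infl$calA
  a_infl <- infl$a_infl
  k <- spec$kind
  if (k == "unit") {
    w <- rep(1, n); Lw <- matrix(0, n, n)
  } else if (k == "stabilized") {
    w <- a; Lw <- a_infl
  } else if (k == "survival") {
    w <- 1 - Fv; Lw <- -calA
  } else if (k == "fh") {
    w <- Fv^spec$r * (1 - Fv)^spec$s
    Lw <- fh_deriv(Fv, spec$r, spec$s) * calA
  } else if (k == "stabilized_survival") {
    w <- a * (1 - Fv)
    Lw <- (1 - Fv) * a_infl - a * calA
  } else { # stabilized_fh
    fh <- Fv^spec$r * (1 - Fv)^spec$s
    w <- a * fh
    Lw <- fh * a_infl + a * fh_deriv(Fv, spec$r, spec$s) * calA
  }
  structure(list(w = w, Lw = Lw, spec = spec, label = weight_label(spec)),
            class = "dt_weight")
}

#' @export
print.dt_weight <- function(x, ...) {
  cat(sprintf("IPW time-varying weight: %s\n", x$label))
  cat(sprintf("  values at event times in [%.4g, %.4g]\n", min(x$w), max(x$w)))
  invisible(x)
}
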
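#' Doubly truncated samples
#'
#' A doubly truncated sample records, for each subject, an event time `T`
#' together with the left and right truncation times `U` and `V` of the
#' random observation window.  The subject is in the sample only because
#' `U <= T <= V`; events falling outside their window are never seen.
#' Covariates are time-fixed numeric columns.
#'
#' @param T numeric vector of event times.
#' @param U numeric vector of left truncation times.
#' @param V numeric vector of right truncation times.
#' @param X optional numeric matrix or data frame of covariates (one row
#'   per subject), or `NULL` for a covariate-free sample.
#' @param ids optional vector of subject labels.
#'
#' @return A `data.frame` of class `"dt_sample"` with columns `T`, `U`,
#'   `V`, any covariates, and an optional `id` column.  Row order is
#'   preserved throughout the package.
#' @seealso [read_dt_sample()], [validate_dt_sample()], [dt_npmle()]
#' @export
#' @examples
#' s <- dt_sample(T = c(1, 2), U = c(0, 1), V = c(2, 3))
#' validate_dt_sample(s)
dt_sample <- function(T, U, V, X = NULL, ids = NULL) {
  d <- data.frame(T = as.numeric(T), U = as.numeric(U), V = as.numeric(V))
  if (!is.null(X)) {
    X <- as.data.frame(X)
    if (nrow(X) != nrow(d))
      stop("covariate block must have one row per subject")
    bad <- intersect(names(X), c("T", "U", "V", "id"))
    if (length(bad))
      stop("covariate names clash with reserved columns: ",
           paste(bad, collapse = ", "))
    d <- cbind(d, X)
  }
  if (!is.null(ids)) d$id <- ids
  class(d) <- c("dt_sample", "data.frame")
  attr(d, "covariates") <- if (is.null(X)) character(0) else names(X)
  viol <- validate_dt_sample(d)
  if (length(viol))
    stop("invalid doubly truncated sample:\n  ",
         paste(viol, collapse = "\n  "))
  d
}

#' Validate a doubly truncated sample
#'
#' Checks the structural invariants of a doubly truncated sample: at least
#' two subjects, all times finite and non-missing, `U <= T <= V` for every
#' row, and strictly positive window length `V - U`.  Nothing is fixed or
#' dropped; every violation is reported.
#'
#' @param sample a data frame with columns `T`, `U`, `V` (and optionally
#'   covariates), e.g. from [dt_sample()] or [read_dt_sample()].
#' @return A character vector of violation messages, empty when the sample
#'   is valid.
#' @export
validate_dt_sample <- function(sample) {
  out <- character(0)
  need <- c("T", "U", "V")
  miss <- setdiff(need, names(sample))
  if (length(miss))
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  n <- nrow(sample)
  if (n < 2) out <- c(out, "n >= 2 required")
  cols <- setdiff(names(sample), "id")
  for (cl in cols) {
    v <- sample[[cl]]
    if (!is.numeric(v)) {
      out <- c(out, sprintf("column '%s' is not numeric", cl))
      next
    }
    bad <- which(!is.finite(v))
    if (length(bad))
      out <- c(out, sprintf("column '%s' has missing/non-finite values in row(s) %s",
                            cl, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (all(vapply(need, function(cl) is.numeric(sample[[cl]]), logical(1)))) {
    Tt <- sample$T; U <- sample$U; V <- sample$V
    ok <- is.finite(Tt) & is.finite(U) & is.finite(V)
    bad <- which(ok & U > Tt)
    for (i in bad) out <- c(out, sprintf("row %d: U > T (%g > %g)", i, U[i], Tt[i]))
    bad <- which(ok & Tt > V)
    for (i in bad) out <- c(out, sprintf("row %d: T > V (%g > %g)", i, Tt[i], V[i]))
    bad <- which(ok & V - U <= 0)
    for (i in bad) out <- c(out, sprintf("row %d: V - U <= 0", i))
  }
  out
}

#' Read a doubly truncated sample from CSV
#'
#' The file must have a header with columns `T`, `U`, `V`; covariates are
#' further numeric columns selected by name.  Times are raw numbers on a
#' common scale (no date parsing).
#'
#' @param path path to a CSV file.
#' @param covariate_names character vector of covariate column names to
#'   keep (default: none).
#' @return A validated [dt_sample()].
#' @export
read_dt_sample <- function(path, covariate_names = character(0)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("T", "U", "V", covariate_names)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("input file is missing column(s): ", paste(miss, collapse = ", "))
  X <- if (length(covariate_names)) d[covariate_names] else NULL
  ids <- if ("id" %in% names(d)) d$id else NULL
  dt_sample(d$T, d$U, d$V, X = X, ids = ids)
}

#' Write a doubly truncated sample to CSV
#'
#' @param sample a [dt_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dt_sample <- function(sample, path) {
  utils::write.csv(as.data.frame(sample), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.dt_sample <- function(x, ...) {
  cv <- attr(x, "covariates")
  cat(sprintf("Doubly truncated sample: %d subjects, %d covariate(s)%s\n",
              nrow(x), length(cv),
              if (length(cv)) paste0(" (", paste(cv, collapse = ", "), ")") else ""))
  cat(sprintf("  event times in [%g, %g]\n", min(x$T), max(x$T)))
  NextMethod()
}

# Extract the covariate matrix (possibly 0-column) from a sample.
sample_covariates <- function(sample, covariate_names = NULL) {
  if (is.null(covariate_names))
    covariate_names <- attr(sample, "covariates")
  if (is.null(covariate_names))
    covariate_names <- setdiff(names(sample), c("T", "U", "V", "id"))
  if (!length(covariate_names))
    return(matrix(numeric(0), nrow = nrow(sample), ncol = 0))
  as.matrix(as.data.frame(sample)[covariate_names])
}
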
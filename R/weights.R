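#' Validate a correlation matrix
#'
#' Checks that a matrix is a valid correlation matrix: square, symmetric,
#' unit diagonal, off-diagonal entries in \[-1, 1\], and positive
#' semi-definite up to a small eigenvalue tolerance.
#'
#' @param C numeric matrix of pairwise endpoint correlations.
#' @param tol symmetry / diagonal tolerance.
#' @param psd_tol smallest eigenvalue allowed (negative values beyond this
#'   tolerance are rejected).
#'
#' @return `C`, invisibly, with dimnames preserved. Errors name the first
#'   offending entry.
#' @export
validate_correlation <- function(C, tol = 1e-8, psd_tol = 1e-8) {
  if (!is.matrix(C) || !is.numeric(C))
    stop("correlation matrix must be a numeric matrix")
  m <- nrow(C)
  if (ncol(C) != m)
    stop("correlation matrix must be square; got ", m, " x ", ncol(C))
  if (m < 2)
    stop("need at least 2 endpoints; got m = ", m)
  if (anyNA(C) || any(!is.finite(C)))
    stop("correlation matrix contains missing or non-finite values")
  asym <- abs(C - t(C))
  if (any(asym > tol)) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("correlation matrix is not symmetric: entry [%d, %d] = %g but [%d, %d] = %g",
                 ij[1], ij[2], C[ij[1], ij[2]], ij[2], ij[1], C[ij[2], ij[1]]))
  }
  dbad <- which(abs(diag(C) - 1) > tol)
  if (length(dbad))
    stop(sprintf("diagonal entry [%d, %d] = %g; must be exactly 1",
                 dbad[1], dbad[1], C[dbad[1], dbad[1]]))
  off <- C; diag(off) <- 0
  obad <- which(abs(off) > 1 + tol, arr.ind = TRUE)
  if (nrow(obad))
    stop(sprintf("correlation [%d, %d] = %g is outside [-1, 1]",
                 obad[1, 1], obad[1, 2], C[obad[1, 1], obad[1, 2]]))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -psd_tol)
    stop(sprintf("correlation matrix is not positive semi-definite (smallest eigenvalue %g)",
                 min(ev)))
  invisible(C)
}

## weights from an already-validated correlation matrix (hot path for sims)
.weights_from_cor <- function(C) 1 / rowSums(C^2)

#' Endpoint weights from a correlation matrix
#'
#' Computes the per-endpoint weights \eqn{w_i = (\sum_j r_{ij}^2)^{-1}} (the
#' sum runs over the full row of the correlation matrix, including the unit
#' diagonal term). The weight of an endpoint is 1 when it is uncorrelated
#' with every other endpoint and shrinks towards \eqn{1/m} as it becomes
#' collinear with the rest. Their sum \eqn{W = \sum_i w_i} estimates the
#' number of effective (quasi-independent) endpoints: \eqn{W = m} for the
#' identity matrix, \eqn{W = 1} when all correlations are \eqn{\pm 1}.
#'
#' @param C an m x m correlation matrix (sample or assumed true), m >= 2.
#' @param validate check matrix invariants first (default `TRUE`).
#'
#' @return An object of class `"endpoint_weights"`: a list with components
#'   `w` (per-endpoint weights), `W` (their sum, the effective number of
#'   endpoints), `sumsq` (\eqn{\sum_i w_i^2}, the variance scale of the test
#'   statistic), `m`, and `labels`.
#'
#' @examples
#' compute_weights(diag(3))               # independent: w = (1,1,1), W = 3
#' C <- matrix(c(1, .6, .6, 1), 2)
#' compute_weights(C)                     # w_i = 1/(1 + .36), W ~ 1.47
#' @export
compute_weights <- function(C, validate = TRUE) {
  if (validate) validate_correlation(C)
  w <- .weights_from_cor(C)
  labels <- rownames(C)
  if (is.null(labels)) labels <- paste0("E", seq_along(w))
  names(w) <- labels
  structure(
    list(w = w, W = sum(w), sumsq = sum(w^2), m = length(w), labels = labels),
    class = "endpoint_weights"
  )
}

#' @export
print.endpoint_weights <- function(x, digits = 4, ...) {
  cat("Endpoint weights (m =", x$m, ")\n")
  print(round(x$w, digits))
  cat("Effective number of endpoints W =", format(x$W, digits = digits + 2),
      "; sum of squared weights =", format(x$sumsq, digits = digits + 2), "\n")
  invisible(x)
}

## coerce weights argument: endpoint_weights object or bare numeric vector
.as_weights <- function(w) {
  if (inherits(w, "endpoint_weights")) return(w)
  if (is.numeric(w) && length(w) >= 1 && all(is.finite(w)) && all(w > 0)) {
    labels <- names(w)
    if (is.null(labels)) labels <- paste0("E", seq_along(w))
    return(structure(
      list(w = as.numeric(w), W = sum(w), sumsq = sum(w^2),
           m = length(w), labels = labels),
      class = "endpoint_weights"
    ))
  }
  stop("weights must be an 'endpoint_weights' object or a positive numeric vector")
}
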
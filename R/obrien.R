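#' O'Brien's OLS global test
#'
#' The ordinary least squares global test for a common standardised effect
#' across endpoints: per-endpoint t statistics are summed and scaled by the
#' correlation structure,
#' \deqn{T_{OLS} = \sum_k t_k / \sqrt{1^T \hat{R} 1},}
#' where \eqn{\hat{R}} is the sample correlation matrix (pooled within-group
#' for two-group designs, correlation of the differences for paired
#' designs). The one-sided upper-tail p-value is taken from a t reference
#' distribution. The test is powerful when all effects share one direction
#' and size, and insensitive to balanced bidirectional effects.
#'
#' @param data endpoint table as in [prediction_test()].
#' @param design `"paired"` or `"two-group"`.
#' @param group grouping column name for two-group designs.
#' @param direction optional per-endpoint orientation (+1/-1): endpoints are
#'   multiplied by it before testing, so that "improvement" is positive on
#'   every endpoint. Default leaves the data as is.
#' @param df degrees of freedom for the reference distribution; default
#'   `N - 2` for two-group (N total) and `n - 1` for paired. Several
#'   small-sample approximations exist in the literature; this one is
#'   configurable because the approximation can be poor for very small n.
#'
#' @return An object of class `"obrien_ols"`: list with `statistic`
#'   (T_OLS), `p.value` (one-sided, upper tail), `df`, `per_endpoint_t`,
#'   and `design`.
#'
#' @examples
#' set.seed(1)
#' d <- make_dataset(diag(4), delta = rep(0.5, 4), n = 20, design = "two-group")
#' ols_test(d, design = "two-group")
#' @export
ols_test <- function(data, design = c("paired", "two-group"), group = "group",
                     direction = NULL, df = NULL) {
  design <- match.arg(design)
  if (design == "two-group") {
    dfr <- as.data.frame(data)
    if (!group %in% names(dfr))
      stop("two-group design requires a '", group, "' column")
    g <- factor(dfr[[group]])
    if (nlevels(g) != 2)
      stop("grouping column '", group, "' must have exactly 2 levels")
    X <- as.matrix(dfr[setdiff(names(dfr), group)])
    if (!is.null(direction)) X <- sweep(X, 2, direction_predictions(direction), `*`)
    x1 <- X[g == levels(g)[1], , drop = FALSE]
    x2 <- X[g == levels(g)[2], , drop = FALSE]
    n1 <- nrow(x1); n2 <- nrow(x2)
    if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
    v1 <- apply(x1, 2, stats::var)
    v2 <- apply(x2, 2, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (any(sp2 == 0)) {
      k <- which(sp2 == 0)[1]
      stop("endpoint '", colnames(X)[k], "' has zero pooled variance")
    }
    tk <- (colMeans(x2) - colMeans(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    centred <- rbind(sweep(x1, 2, colMeans(x1)), sweep(x2, 2, colMeans(x2)))
    R <- stats::cor(centred)
    df_ref <- if (is.null(df)) n1 + n2 - 2L else df
  } else {
    X <- as.matrix(as.data.frame(data))
    if (!is.null(direction)) X <- sweep(X, 2, direction_predictions(direction), `*`)
    n <- nrow(X)
    if (n < 2) stop("need at least 2 subjects")
    s <- apply(X, 2, stats::sd)
    if (any(s == 0)) {
      k <- which(s == 0)[1]
      stop("endpoint '", colnames(X)[k], "' has zero variance")
    }
    tk <- colMeans(X) / (s / sqrt(n))
    R <- stats::cor(X)
    df_ref <- if (is.null(df)) n - 1L else df
  }
  m <- length(tk)
  if (m == 1) {
    stat <- tk
  } else {
    if (anyNA(R)) stop("sample correlation matrix contains NA")
    stat <- sum(tk) / sqrt(sum(R))
  }
  structure(
    list(statistic = unname(stat),
         p.value = stats::pt(unname(stat), df = df_ref, lower.tail = FALSE),
         df = df_ref, per_endpoint_t = tk, design = design, m = m),
    class = "obrien_ols"
  )
}

#' @export
print.obrien_ols <- function(x, digits = 6, ...) {
  cat("\n\tO'Brien's OLS global test (", x$design, " design)\n\n", sep = "")
  cat("m =", x$m, "endpoints, df =", x$df, "\n")
  cat("T_OLS =", signif(x$statistic, digits),
      "  one-sided p-value =", signif(x$p.value, digits), "\n\n")
  invisible(x)
}
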
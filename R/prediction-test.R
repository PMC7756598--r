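#' Prediction-based global test for multiple endpoints
#'
#' Tests the global null hypothesis \eqn{H_0: \phi \le \phi_0} that the
#' researcher's ability to predict the direction of each endpoint's effect
#' is no better than the hypothesised value \eqn{\phi_0}, against
#' \eqn{H_1: \phi > \phi_0}. Each correct directional prediction contributes
#' its endpoint's weight \eqn{w_i = (\sum_j r_{ij}^2)^{-1}} to the statistic
#' \eqn{T_m = \sum_i p_i w_i}, so that correctly predicting endpoints that
#' are nearly independent of the rest counts for more than predicting
#' near-duplicates.
#'
#' Supply either a raw endpoint table plus direction predictions (the
#' correlation matrix and observed effect signs are computed from the data
#' according to `design`), or a precomputed `correlation` matrix plus the
#' binary `outcomes` vector.
#'
#' The rejection rule is \eqn{p \le \alpha} and, by default, additionally
#' \eqn{T_m \ge 1}: at least one effective endpoint must be correctly
#' predicted, which under perfect dependence forces every single prediction
#' to be correct.
#'
#' @param data data frame or matrix of endpoint measurements, one row per
#'   experimental unit, one column per endpoint. For `design = "paired"`
#'   rows are within-subject (post minus pre) differences; for
#'   `design = "two-group"` a `group` column with exactly two levels
#'   identifies the groups and effects are group-2 minus group-1 means.
#' @param predictions per-endpoint direction predictions (+1/-1 or
#'   "up"/"down"); required with `data`.
#' @param correlation precomputed m x m correlation matrix (alternative to
#'   `data`).
#' @param outcomes binary vector of prediction outcomes (1 = correct);
#'   required with `correlation` or `weights`.
#' @param weights precomputed endpoint weights (an [compute_weights()]
#'   object or positive numeric vector), for when only published weights
#'   are available rather than the correlation matrix itself.
#' @param design study design, `"paired"` or `"two-group"`.
#' @param group name of the grouping column for two-group designs.
#' @param phi0 null predictive ability; default 0.5 (chance). Values below
#'   0.5 are rarely defensible.
#' @param alpha significance level.
#' @param method `"exact"` enumerates the null distribution, `"normal"`
#'   uses the normal approximation, `"auto"` (default) picks exact for
#'   `m <= exact_limit` and normal above.
#' @param cor_method correlation estimator passed to [stats::cor()];
#'   Pearson by default.
#' @param require_t_ge_1 apply the \eqn{T_m \ge 1} rejection gate
#'   (default `TRUE`).
#' @param exact_limit largest m for which `method = "auto"` uses the exact
#'   distribution (default 20).
#' @param max_exact_m hard enumeration cap for `method = "exact"`
#'   (default 25).
#' @param tie_tolerance absolute tolerance for tie handling in the exact
#'   distribution.
#'
#' @return An object of class `"prediction_test"` (printed like an htest):
#'   list with `statistic`, `p.value`, `method` (`"exact"` or `"normal"`),
#'   `reject`, `phi0`, `alpha`, `weights` (the [compute_weights()] object),
#'   `W`, `outcomes`, `effects` (when computed from data),
#'   `require_t_ge_1`, `n` (units used) and `design`.
#'
#' @examples
#' ex <- asl_example()
#' prediction_test(weights = ex$weights, outcomes = ex$outcomes)
#' @export
prediction_test <- function(data = NULL, predictions = NULL,
                            correlation = NULL, outcomes = NULL,
                            weights = NULL,
                            design = c("paired", "two-group"),
                            group = "group",
                            phi0 = 0.5, alpha = 0.05,
                            method = c("auto", "exact", "normal"),
                            cor_method = c("pearson", "spearman", "kendall"),
                            require_t_ge_1 = TRUE,
                            exact_limit = 20, max_exact_m = 25,
                            tie_tolerance = 1e-9) {
  design <- match.arg(design)
  method <- match.arg(method)
  cor_method <- match.arg(cor_method)
  .check_phi0(phi0)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number strictly between 0 and 1")

  effects <- NULL
  n_units <- NA_integer_
  if (!is.null(data)) {
    if (is.null(predictions))
      stop("predictions are required when raw data are supplied")
    summ <- .summarise_endpoints(data, design = design, group = group,
                                 cor_method = cor_method)
    effects <- summ$effects
    n_units <- summ$n
    w <- compute_weights(summ$correlation)
    p <- evaluate_predictions(effects, predictions)
  } else if (!is.null(weights)) {
    if (is.null(outcomes))
      stop("outcomes are required when precomputed weights are supplied")
    w <- .as_weights(weights)
    p <- .check_outcomes(outcomes, w$m)
  } else if (!is.null(correlation)) {
    if (is.null(outcomes))
      stop("outcomes are required when a correlation matrix is supplied")
    w <- compute_weights(correlation)
    p <- .check_outcomes(outcomes, w$m)
  } else {
    stop("supply either data + predictions, correlation + outcomes, or weights + outcomes")
  }

  m <- w$m
  if (m < 2)
    stop("m = 1 is not a multiple-endpoint problem; use a one-sample sign or t test")

  t_obs <- sum(p * w$w)
  used <- if (method == "auto") {
    if (m <= exact_limit) "exact" else "normal"
  } else method
  pval <- if (used == "exact") {
    if (m > max_exact_m)
      stop("m = ", m, " exceeds the enumeration cap (", max_exact_m,
           "); use method = \"normal\"")
    .tail_prob(w, phi0, t_obs, tie_tolerance = tie_tolerance, upper = TRUE)
  } else {
    normal_pvalue(t_obs, w, phi0)
  }
  reject <- (pval <= alpha) && (!require_t_ge_1 || t_obs >= 1)

  structure(
    list(statistic = t_obs, p.value = pval, method = used, reject = reject,
         phi0 = phi0, alpha = alpha, weights = w, W = w$W,
         outcomes = as.integer(p), effects = effects,
         require_t_ge_1 = require_t_ge_1, n = n_units, design = design),
    class = "prediction_test"
  )
}

#' @export
print.prediction_test <- function(x, digits = 6, ...) {
  cat("\n\tPrediction-based global test for multiple endpoints\n\n")
  cat("m =", x$weights$m, "endpoints, effective endpoints W =",
      signif(x$W, digits), "\n")
  cat("correct predictions:", sum(x$outcomes), "of", x$weights$m,
      " (outcome vector ", paste(x$outcomes, collapse = ""), ")\n", sep = " ")
  cat("T_m =", signif(x$statistic, digits),
      "  p-value =", signif(x$p.value, digits),
      " (", x$method, " method, phi0 =", x$phi0, ")\n")
  gate <- if (x$require_t_ge_1) " and T_m >= 1" else ""
  cat("decision at alpha =", x$alpha, ":",
      if (x$reject) "reject H0: phi <=" else "fail to reject H0: phi <=",
      x$phi0, paste0("(rule: p <= alpha", gate, ")"), "\n\n")
  invisible(x)
}

#' Minimum number of endpoints for a rejectable test
#'
#' Because the exact distribution is discrete, some (phi0, alpha) pairs can
#' never yield a rejection: even a perfect prediction record has null
#' probability \eqn{\phi_0^m}. Returns the smallest m with
#' \eqn{\phi_0^m \le \alpha}; at that m only an all-correct record rejects.
#'
#' @param phi0 null predictive ability in (0, 1).
#' @param alpha significance level in (0, 1).
#'
#' @return integer, the minimum feasible number of endpoints.
#' @examples
#' minimum_required_m(0.5)        # 5
#' minimum_required_m(0.9)        # 29
#' @export
minimum_required_m <- function(phi0, alpha = 0.05) {
  .check_phi0(phi0)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  m <- max(1L, as.integer(ceiling(log(alpha) / log(phi0) - 1e-12)))
  while (phi0^m > alpha) m <- m + 1L
  while (m > 1L && phi0^(m - 1L) <= alpha) m <- m - 1L
  m
}

## Per-design summary: observed effect estimates, correlation matrix for
## weighting, and the number of experimental units.
## paired: rows are within-subject differences; effects are column means and
##   the correlation is taken across subjects' difference vectors.
## two-group: effects are group-2 minus group-1 column means; the correlation
##   is pooled within-group (each group de-meaned first) so between-group
##   shifts do not contaminate the weights.
.summarise_endpoints <- function(data, design, group = "group",
                                 cor_method = "pearson") {
  if (design == "two-group") {
    df <- as.data.frame(data)
    if (!group %in% names(df))
      stop("two-group design requires a '", group, "' column")
    g <- factor(df[[group]])
    if (nlevels(g) != 2)
      stop("grouping column '", group, "' must have exactly 2 levels; found ",
           nlevels(g))
    X <- as.matrix(df[setdiff(names(df), group)])
    if (!is.numeric(X)) stop("endpoint columns must be numeric")
    x1 <- X[g == levels(g)[1], , drop = FALSE]
    x2 <- X[g == levels(g)[2], , drop = FALSE]
    if (nrow(x1) < 2 || nrow(x2) < 2)
      stop("need at least 2 observations per group")
    effects <- colMeans(x2) - colMeans(x1)
    centred <- rbind(sweep(x1, 2, colMeans(x1)), sweep(x2, 2, colMeans(x2)))
    C <- stats::cor(centred, method = cor_method)
    n <- nrow(X)
  } else {
    X <- as.matrix(as.data.frame(data))
    if (!is.numeric(X)) stop("endpoint columns must be numeric")
    if (nrow(X) < 2) stop("need at least 2 subjects")
    effects <- colMeans(X)
    C <- stats::cor(X, method = cor_method)
    n <- nrow(X)
  }
  if (anyNA(C))
    stop("correlation matrix contains NA (constant endpoint column?)")
  list(effects = effects, correlation = C, n = n)
}
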
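#' Directional predictions for a set of endpoints
#'
#' Normalises a vector of a priori direction predictions to +1 / -1. Accepts
#' numeric signs or the strings "up"/"down" (case-insensitive, also
#' "increase"/"decrease", "+"/"-").
#'
#' @param x numeric vector of +1/-1, or character vector of directions.
#' @param labels optional endpoint labels (defaults to `names(x)`).
#'
#' @return integer vector of +1/-1 with endpoint labels as names.
#' @export
direction_predictions <- function(x, labels = names(x)) {
  if (is.character(x) || is.factor(x)) {
    key <- tolower(trimws(as.character(x)))
    up <- c("up", "increase", "+", "+1", "1", "pos", "positive")
    down <- c("down", "decrease", "-", "-1", "neg", "negative")
    s <- ifelse(key %in% up, 1L, ifelse(key %in% down, -1L, NA_integer_))
    if (anyNA(s))
      stop("unrecognised direction(s): ",
           paste(unique(x[is.na(s)]), collapse = ", "),
           " (use +1/-1 or up/down)")
    x <- s
  }
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("predictions must be finite numeric signs or direction strings")
  if (any(x == 0))
    stop("prediction of 0 at position ", which(x == 0)[1],
         "; every endpoint needs a direction (+1 or -1)")
  s <- as.integer(sign(x))
  if (!is.null(labels)) names(s) <- labels
  s
}

#' Score directional predictions against observed effects
#'
#' Compares the sign of each observed per-endpoint effect estimate (paired:
#' mean within-subject difference; two-group: group-2 mean minus group-1
#' mean) with the predicted direction. An exactly zero observed effect counts
#' as an incorrect prediction, the conservative convention for ties.
#'
#' @param effects numeric vector of observed per-endpoint effect estimates.
#' @param predictions direction predictions; anything accepted by
#'   [direction_predictions()].
#'
#' @return binary integer vector `p` (1 = direction correctly predicted),
#'   with attribute `n_correct`.
#'
#' @examples
#' evaluate_predictions(c(0.16, 0.44, -1.49, 1.07, 0.97, -0.24), rep(1, 6))
#' @export
evaluate_predictions <- function(effects, predictions) {
  signs <- direction_predictions(predictions)
  if (!is.numeric(effects))
    stop("effects must be numeric")
  if (any(!is.finite(effects)))
    stop("non-finite effect estimate at position ", which(!is.finite(effects))[1])
  if (length(effects) != length(signs))
    stop("length mismatch: ", length(effects), " effects vs ",
         length(signs), " predictions")
  p <- as.integer(sign(effects) == signs & effects != 0)
  names(p) <- names(signs)
  attr(p, "n_correct") <- sum(p)
  p
}

#' Weighted prediction test statistic
#'
#' The statistic \eqn{T_m = \sum_i p_i w_i}: the total weight of the
#' correctly predicted endpoints, i.e. the number of effective endpoints
#' correctly predicted. Bounded by \eqn{0 \le T_m \le W}.
#'
#' @param p binary outcome vector (1 = correct), as from
#'   [evaluate_predictions()].
#' @param w endpoint weights ([compute_weights()] object or numeric vector).
#'
#' @return the scalar statistic.
#' @examples
#' test_statistic(c(1, 1, 0, 1, 1, 0), c(0.46, 0.41, 0.68, 0.48, 0.39, 0.40))
#' @export
test_statistic <- function(p, w) {
  w <- .as_weights(w)
  p <- .check_outcomes(p, w$m)
  sum(p * w$w)
}

.check_outcomes <- function(p, m) {
  if (!is.numeric(p) || any(!(p %in% c(0, 1))))
    stop("prediction outcomes must be a binary 0/1 vector")
  if (length(p) != m)
    stop("length mismatch: ", length(p), " outcomes vs ", m, " weights")
  as.integer(p)
}
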
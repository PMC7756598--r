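#' Random correlation matrix by the C-vine method
#'
#' Draws a random m x m positive-definite correlation matrix by the vine
#' construction: partial correlations are drawn layer by layer from a Beta
#' distribution rescaled to (-1, 1), with shape parameters decaying by
#' layer, and composed recursively into full correlations. With
#' `alphad = 1` (the LKJ shape eta = 1) the draw is uniform over the space
#' of positive-definite correlation matrices; in dimension 2 the single
#' off-diagonal correlation is then uniform on (-1, 1).
#'
#' @param m number of endpoints (>= 2).
#' @param alphad vine shape parameter; 1 gives the uniform distribution.
#' @param seed optional integer seed for reproducibility.
#'
#' @return an m x m correlation matrix (symmetric, unit diagonal,
#'   positive definite).
#'
#' @examples
#' C <- random_correlation(5, seed = 42)
#' min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
random_correlation <- function(m, alphad = 1, seed = NULL) {
  if (!is.numeric(m) || length(m) != 1 || m < 2 || m != round(m))
    stop("m must be a single integer >= 2")
  if (!is.numeric(alphad) || alphad <= 0)
    stop("alphad must be positive")
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(m)
  P <- matrix(0, m, m)     # partial correlations, layer k in row k
  R <- diag(m)
  beta <- alphad + (m - 1) / 2
  for (k in seq_len(m - 1)) {
    beta <- beta - 1 / 2
    i <- (k + 1):m
    P[k, i] <- 2 * stats::rbeta(length(i), beta, beta) - 1
    rho <- P[k, i]
    if (k > 1) {
      for (l in (k - 1):1) {
        rho <- rho * sqrt((1 - P[l, i]^2) * (1 - P[l, k]^2)) + P[l, i] * P[l, k]
      }
    }
    R[k, i] <- rho
    R[i, k] <- rho
  }
  R
}

#' Per-endpoint standardised effect vectors for simulation scenarios
#'
#' Builds the delta vector (standardised mean differences, SD units) for the
#' stock simulation scenarios:
#' \describe{
#'   \item{const}{`base` on every endpoint.}
#'   \item{bidirectional-const}{`+base` on the second half of the endpoints,
#'     `-base` on the first half.}
#'   \item{stagger}{endpoint k gets `base * k / m`, k = 1..m.}
#'   \item{bidirectional-stagger}{staggered magnitudes with the first half
#'     (the smallest ones) negated.}
#'   \item{spike}{endpoint 1 at `spike`, all others at `spike_rest`.}
#'   \item{null}{all zeros.}
#' }
#'
#' @param scenario scenario label.
#' @param m number of endpoints.
#' @param base base effect magnitude in SD units (default 0.5).
#' @param spike,spike_rest magnitudes for the spike scenario (defaults 1
#'   and 0.1).
#'
#' @return numeric length-m delta vector.
#' @examples
#' effect_scenario("stagger", 4)    # 0.125 0.250 0.375 0.500
#' @export
effect_scenario <- function(scenario = c("const", "bidirectional-const",
                                         "stagger", "bidirectional-stagger",
                                         "spike", "null"),
                            m, base = 0.5, spike = 1, spike_rest = 0.1) {
  scenario <- match.arg(scenario)
  stopifnot(m >= 1)
  half <- floor(m / 2)
  switch(scenario,
    "const" = rep(base, m),
    "bidirectional-const" = c(rep(-base, half), rep(base, m - half)),
    "stagger" = base * seq_len(m) / m,
    "bidirectional-stagger" = {
      d <- base * seq_len(m) / m
      d[seq_len(half)] <- -d[seq_len(half)]
      d
    },
    "spike" = c(spike, rep(spike_rest, m - 1)),
    "null" = rep(0, m)
  )
}

#' Simulate multivariate normal endpoint data
#'
#' Generates an endpoint table from a multivariate normal distribution with
#' unit variances (so `delta` is in SD units) and correlation matrix `C`.
#' Two-group design: n rows from MVN(0, C) labelled group 1 and n rows from
#' MVN(delta, C) labelled group 2. Paired design: n rows of within-subject
#' differences from MVN(delta, C).
#'
#' @param C correlation matrix.
#' @param delta length-m vector of standardised effects (or a scenario
#'   label, resolved via [effect_scenario()]).
#' @param n observations per group (two-group) or subjects (paired).
#' @param design `"two-group"` or `"paired"`.
#' @param seed optional integer seed.
#' @param labels endpoint column labels (default `E1..Em` or the dimnames
#'   of `C`).
#'
#' @return a data frame with one column per endpoint plus, for two-group
#'   designs, a `group` factor column.
#' @export
make_dataset <- function(C, delta = 0, n, design = c("two-group", "paired"),
                         seed = NULL, labels = NULL) {
  design <- match.arg(design)
  validate_correlation(C)
  m <- nrow(C)
  if (is.character(delta)) delta <- effect_scenario(delta, m)
  if (length(delta) == 1) delta <- rep(delta, m)
  if (length(delta) != m)
    stop("delta has length ", length(delta), " but C has ", m, " endpoints")
  if (n < 2) stop("need n >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) {
    labels <- rownames(C)
    if (is.null(labels)) labels <- paste0("E", seq_len(m))
  }
  if (design == "two-group") {
    x1 <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = C)
    x2 <- MASS::mvrnorm(n, mu = delta, Sigma = C)
    out <- as.data.frame(rbind(x1, x2))
    names(out) <- labels
    out$group <- factor(rep(c(1, 2), each = n))
  } else {
    out <- as.data.frame(MASS::mvrnorm(n, mu = delta, Sigma = C))
    names(out) <- labels
  }
  out
}
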
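#' ASL cerebral blood flow worked example (published summary values)
#'
#' Summary quantities from a pre-post exercise-intervention study measuring
#' arterial spin labeling (ASL, a cerebral blood flow proxy) in six brain
#' regions of 11 older adults. The investigator predicted an increase in
#' every region; four of the six observed pre-post mean differences were
#' positive. The raw subject-level data are not publicly deposited, so this
#' fixture carries only the published per-region summary values: the mean
#' pre-post differences, the endpoint weights derived from the sample
#' correlation matrix of the differences, and the resulting
#' prediction-outcome vector. With these weights the test statistic is
#' \eqn{T_m = 0.46 + 0.41 + 0.48 + 0.39 = 1.74}, which at
#' \eqn{\phi_0 = 0.5} fails to reach significance at \eqn{\alpha = 0.05}.
#'
#' @return list with `labels` (brain regions), `effects` (observed mean
#'   pre-post differences), `predictions` (all +1: increase), `outcomes`
#'   (1 = direction correctly predicted), `weights` (published rounded
#'   endpoint weights as an [compute_weights()]-style object), `n`
#'   (subjects) and `design`.
#'
#' @examples
#' ex <- asl_example()
#' test_statistic(ex$outcomes, ex$weights)   # 1.74
#' @export
asl_example <- function() {
  labels <- c("BA46", "FrontalMid", "Hippocampus", "M1",
              "SuperiorParietal", "Precuneus")
  effects <- c(0.16, 0.44, -1.49, 1.07, 0.97, -0.24)
  w <- c(0.46, 0.41, 0.68, 0.48, 0.39, 0.40)
  names(effects) <- names(w) <- labels
  predictions <- stats::setNames(rep(1L, 6), labels)
  list(
    labels = labels,
    effects = effects,
    predictions = predictions,
    outcomes = stats::setNames(c(1L, 1L, 0L, 1L, 1L, 0L), labels),
    weights = .as_weights(w),
    n = 11L,
    design = "paired"
  )
}
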
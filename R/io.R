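#' Read an endpoint data table
#'
#' Reads a CSV or TSV file (dialect chosen by extension; `.tsv`/`.txt` are
#' tab-delimited) with a header row of endpoint labels and one row per
#' experimental unit. For two-group designs a `group` column with exactly
#' two levels is required; all other columns must be numeric with no
#' missing values (violations are reported with row/column coordinates).
#'
#' @param path file path.
#' @param design `"paired"` or `"two-group"`.
#' @param group grouping column name (two-group designs).
#'
#' @return a validated data frame.
#' @export
read_endpoint_table <- function(path, design = c("paired", "two-group"),
                                group = "group") {
  design <- match.arg(design)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty table: ", path)
  ep_cols <- setdiff(names(df), if (design == "two-group") group else character())
  if (design == "two-group") {
    if (!group %in% names(df))
      stop("two-group design requires a '", group, "' column in ", path)
    lv <- unique(df[[group]])
    if (length(lv) != 2)
      stop("grouping column '", group, "' has ", length(lv),
           " level(s); exactly 2 required")
  }
  for (cn in ep_cols) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop("non-numeric value in column '", cn, "', row ",
           if (is.na(bad)) 1 else bad)
    }
    if (anyNA(col))
      stop("missing value in column '", cn, "', row ", which(is.na(col))[1])
  }
  df
}

#' Read a direction-predictions file
#'
#' Two-column tab-delimited file: endpoint label and predicted direction
#' (`+1`, `-1`, `up`, or `down`). A header row is optional and detected
#' automatically.
#'
#' @param path file path.
#' @return named integer vector of +1/-1 direction predictions.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("endpoint", "direction"))
  if (nrow(df) == 0) stop("empty predictions file: ", path)
  ## drop a header row if the direction field is not a recognisable direction
  first <- tolower(trimws(as.character(df$direction[1])))
  known <- c("up", "down", "increase", "decrease", "+", "-", "+1", "-1",
             "1", "pos", "neg", "positive", "negative")
  if (!(first %in% known) && nrow(df) > 1) df <- df[-1, , drop = FALSE]
  direction_predictions(df$direction, labels = df$endpoint)
}

#' Write a machine-readable test report
#'
#' Serialises a [prediction_test()] result (and optionally an [ols_test()]
#' comparator result) to JSON at full numeric precision. The report
#' round-trips losslessly through [jsonlite::fromJSON()].
#'
#' @param result a `"prediction_test"` object.
#' @param path output file path.
#' @param ols optional `"obrien_ols"` object to embed as a comparator
#'   block.
#' @param seed optional seed to record for provenance.
#'
#' @return the report list, invisibly.
#' @export
write_report <- function(result, path, ols = NULL, seed = NULL) {
  stopifnot(inherits(result, "prediction_test"))
  report <- list(
    statistic = result$statistic,
    p_value = result$p.value,
    method = result$method,
    decision = if (result$reject) "reject" else "fail-to-reject",
    phi0 = result$phi0,
    alpha = result$alpha,
    require_t_ge_1 = result$require_t_ge_1,
    weights = as.list(result$weights$w),
    W = result$W,
    outcomes = result$outcomes,
    design = result$design,
    software = list(package = "predtest",
                    version = as.character(utils::packageVersion("predtest")))
  )
  if (!is.null(result$effects)) report$effects <- as.list(result$effects)
  if (!is.null(seed)) report$seed <- seed
  if (!is.null(ols)) {
    stopifnot(inherits(ols, "obrien_ols"))
    report$obrien_ols <- list(statistic = ols$statistic,
                              p_value = ols$p.value, df = ols$df)
  }
  ok <- tryCatch({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    TRUE
  }, error = function(e) stop("could not write report to ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(report)
}

#' Write an exact null distribution as TSV
#'
#' Two columns: statistic value and probability.
#'
#' @param dist an [exact_null_distribution()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "exact_null_distribution"))
  utils::write.table(
    data.frame(value = dist$support, probability = dist$probs),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
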
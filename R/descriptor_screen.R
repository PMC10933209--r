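#' Read a labelled compound descriptor table
#'
#' CSV with header `id,logp,logd,vsurf_a,tpsa,label` (`tpsa` optional; lines
#' starting with `#` are comments). `label` is `aggregator` /
#' `non-aggregator` where known. A synthetic example table spanning both
#' classes ships at
#' `system.file("extdata", "compounds_synthetic.csv", package = "scamscreen")`.
#'
#' @param path CSV path.
#' @return A `data.frame` of compound records.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: compound table '%s' does not exist", path))
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "logp", "logd", "vsurf_a", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("compound table is missing column(s): %s (available: %s)",
                 paste(miss, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  if (nrow(df) == 0) stop("compound table is empty")
  bad <- df$label[!df$label %in% c("aggregator", "non-aggregator", "", NA)]
  if (length(bad))
    stop("labels must be 'aggregator' or 'non-aggregator'; got: ",
         paste(unique(bad), collapse = ", "))
  df$id <- as.character(df$id)
  df
}

#' Single-descriptor threshold classifier
#'
#' Baseline screen: predict aggregator when the descriptor crosses the
#' threshold -- strictly, by default, so e.g. the `logD > 3` rule leaves a
#' compound with logD exactly 3 a non-aggregator. Records missing the
#' descriptor are excluded and reported. When experimental labels are
#' present the result is scored against them.
#'
#' @param records A compound `data.frame` from [read_compound_table()].
#' @param descriptor Column name to threshold (e.g. `"logd"`, `"logp"`,
#'   `"vsurf_a"`).
#' @param threshold Decision threshold (the logD rule uses 3).
#' @param direction `"greater_means_aggregator"` (default) or
#'   `"less_means_aggregator"`.
#' @param inclusive Use `>=` / `<=` instead of the strict default.
#' @return Object of class `screen_result`: list with `predictions` (data
#'   frame: id, value, predicted, truth, correct), `success_rate_percent`
#'   (`NA` without labels), `misclassified` (ids), `confusion` (2x2 table),
#'   `excluded` (ids lacking the descriptor), `parameters`.
#' @export
threshold_classify <- function(records, descriptor = "logd", threshold = 3,
                               direction = c("greater_means_aggregator",
                                             "less_means_aggregator"),
                               inclusive = FALSE) {
  direction <- match.arg(direction)
  if (!descriptor %in% names(records))
    stop(sprintf("unknown descriptor '%s'; available columns: %s", descriptor,
                 paste(setdiff(names(records), c("id", "label")),
                       collapse = ", ")))
  v <- records[[descriptor]]
  excluded <- records$id[!is.finite(v)]
  keep <- is.finite(v)
  rec <- records[keep, , drop = FALSE]
  v <- v[keep]
  hit <- if (direction == "greater_means_aggregator") {
    if (inclusive) v >= threshold else v > threshold
  } else {
    if (inclusive) v <= threshold else v < threshold
  }
  pred <- ifelse(hit, "aggregator", "non-aggregator")
  truth <- if ("label" %in% names(rec)) rec$label else rep(NA_character_,
                                                           nrow(rec))
  predictions <- data.frame(id = rec$id, value = v, predicted = pred,
                            truth = truth,
                            correct = !is.na(truth) & pred == truth,
                            stringsAsFactors = FALSE)
  scored <- !is.na(truth) & nzchar(truth)
  sr <- if (any(scored)) success_rate(pred[scored], truth[scored],
                                      ids = rec$id[scored])
        else list(percent = NA_real_, misclassified = character())
  confusion <- if (any(scored))
    table(predicted = pred[scored], truth = truth[scored]) else NULL
  structure(list(predictions = predictions,
                 success_rate_percent = sr$percent,
                 misclassified = sr$misclassified, confusion = confusion,
                 excluded = excluded,
                 parameters = list(descriptor = descriptor,
                                   threshold = threshold,
                                   direction = direction,
                                   inclusive = inclusive)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<screen_result> %s %s %g: %d scored, success %.1f%%; %s\n",
              p$descriptor,
              if (p$direction == "greater_means_aggregator") ">" else "<",
              p$threshold, sum(!is.na(x$predictions$truth)),
              x$success_rate_percent,
              if (length(x$misclassified))
                paste("misclassified:",
                      paste(x$misclassified, collapse = ", "))
              else "none misclassified"))
  invisible(x)
}

#' Success rate of predicted against experimental labels
#'
#' `100 * matches / n`, reported to one decimal, with the misclassified ids.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param ids Optional compound ids (defaults to positions).
#' @return List with `percent`, `n`, `n_correct`, `misclassified`.
#' @export
success_rate <- function(predicted, truth, ids = NULL) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (length(predicted) < 1) stop("need at least one prediction to score")
  if (is.null(ids)) ids <- as.character(seq_along(predicted))
  ok <- predicted == truth
  list(percent = round(100 * sum(ok) / length(ok), 1),
       n = length(ok), n_correct = sum(ok),
       misclassified = ids[!ok])
}

#' Compare MD-derived calls with descriptor screens
#'
#' Per-compound agreement matrix and per-method success rates for any mix of
#' MD aggregation reports and descriptor screens, scored against experimental
#' labels. Compounds missing from a method are marked `not-scored`.
#'
#' @param md_reports Named list of [aggregation_report()]s (names or
#'   `compound_id`s identify the compound), or `NULL`.
#' @param screens Named list of [threshold_classify()] results (name becomes
#'   the method name), or `NULL`.
#' @param truth Named character vector of experimental labels keyed by
#'   compound id.
#' @return Object of class `method_comparison`: list with `table` (data
#'   frame: id, truth, one column per method) and `success` (per-method
#'   success rate over its scored compounds).
#' @export
compare_methods <- function(md_reports = NULL, screens = NULL, truth) {
  stopifnot(!is.null(names(truth)))
  methods <- list()
  if (!is.null(md_reports)) {
    ids <- names(md_reports)
    if (is.null(ids))
      ids <- vapply(md_reports, function(r) as.character(r$compound_id),
                    character(1))
    methods$md <- setNames(
      vapply(md_reports, function(r) r$class, character(1)), ids)
  }
  if (!is.null(screens)) {
    nm <- names(screens)
    if (is.null(nm)) nm <- paste0("screen", seq_along(screens))
    for (i in seq_along(screens)) {
      p <- screens[[i]]$predictions
      methods[[nm[i]]] <- setNames(p$predicted, p$id)
    }
  }
  if (!length(methods)) stop("no methods to compare")
  all_ids <- names(truth)
  shared <- Reduce(union, lapply(methods, names))
  if (!length(intersect(all_ids, shared)))
    stop("no shared compound ids between methods and truth labels")
  tab <- data.frame(id = all_ids, truth = as.character(truth),
                    stringsAsFactors = FALSE)
  success <- numeric(0)
  for (m in names(methods)) {
    calls <- methods[[m]][all_ids]
    calls[is.na(calls)] <- "not-scored"
    tab[[m]] <- unname(calls)
    scored <- calls != "not-scored"
    success[m] <- if (any(scored))
      success_rate(calls[scored], tab$truth[scored])$percent else NA_real_
  }
  structure(list(table = tab, success = success),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> success rates (%):\n")
  print(x$success)
  invisible(x)
}

#' @rdname compare_methods
#' @param comparison A `method_comparison`.
#' @param path Output CSV path.
#' @export
write_comparison_csv <- function(comparison, path) {
  write.csv(comparison$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
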
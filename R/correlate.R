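#' Agreement reports from a paired-measurement table
#'
#' @param pairs data frame with columns `subject` (or `subject_id`),
#'   `metric`, `value_a`, `value_b` — one row per subject and metric.
#' @return Data frame with one row per metric: n, mean error, 95% limits
#'   of agreement, coefficient of repeatability (absolute and % of
#'   mean), ICC.
#' @export
agreement_from_table <- function(pairs) {
  need <- c("metric", "value_a", "value_b")
  if (!all(need %in% names(pairs)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  out <- do.call(rbind, lapply(split(pairs, pairs$metric), function(sub) {
    rep <- agreement_report(sub$value_a, sub$value_b,
                            label = as.character(sub$metric[1]))
    df <- as.data.frame(rep)
    names(df)[1] <- "metric"
    df
  }))
  rownames(out) <- NULL
  out
}

#' Correlate uptake metrics with clinical risk scores
#'
#' Pearson correlation (with two-sided p-value) between every uptake
#' metric column and every risk-score column, matched by subject
#' identifier. Risk scores are externally computed instruments consumed
#' as plain columns; their formulas are outside this package.
#'
#' @param metrics data frame with a subject-identifier column and one
#'   column per uptake metric.
#' @param scores data frame with the same identifier column and one
#'   column per risk score.
#' @param by name of the identifier column (default `"subject_id"`).
#' @return Data frame with columns `metric`, `score`, `r`, `p`, `n`.
#' @export
correlate_risk_scores <- function(metrics, scores, by = "subject_id") {
  if (!by %in% names(metrics) || !by %in% names(scores))
    stop("both tables need an identifier column '", by, "'")
  merged <- merge(metrics, scores, by = by)
  if (nrow(merged) < 3) stop("fewer than 3 matched subjects")
  mcols <- setdiff(names(metrics), by)
  scols <- setdiff(names(scores), by)
  rows <- list()
  for (m in mcols) for (s in scols) {
    pc <- pearson_cor(merged[[m]], merged[[s]])
    rows[[length(rows) + 1L]] <- data.frame(metric = m, score = s,
                                            r = pc$r, p = pc$p, n = pc$n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
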
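#' Assemble a per-culture record
#'
#' Bundles one culture's analysis outputs for aggregation: electrode-level
#' firing/burst metrics, cell-level morphometrics and a colocalization
#' result.
#'
#' @param cultureId culture label.
#' @param condition `"dissociated_2D"` or `"aggregated_3D"`.
#' @param div days in vitro (> 0).
#' @param electrodeMetrics list of per-electrode metric lists (e.g. merged
#'   [rateMetrics()] and [burstMetrics()] fields).
#' @param cellMetrics list of [branchMorphometrics()] results.
#' @param coloc a [colocalize()] result or NULL.
#' @return a list of class `"CultureRecord"`.
#' @export
cultureRecord <- function(cultureId, condition = c("dissociated_2D",
                                                   "aggregated_3D"),
                          div, electrodeMetrics = list(),
                          cellMetrics = list(), coloc = NULL) {
  condition <- match.arg(condition)
  if (div <= 0) stopf("div must be > 0")
  structure(list(cultureId = as.character(cultureId), condition = condition,
                 div = div, electrodeMetrics = electrodeMetrics,
                 cellMetrics = cellMetrics, coloc = coloc),
            class = "CultureRecord")
}

## pull one named metric's values out of a record, searching electrode
## metrics, cell metrics, then the coloc result
metricValues <- function(record, metric) {
  vals <- c(
    unlist(lapply(record$electrodeMetrics, function(m) m[[metric]])),
    unlist(lapply(record$cellMetrics, function(m) m[[metric]])),
    if (!is.null(record$coloc)) record$coloc[[metric]]
  )
  as.numeric(vals[!is.na(vals)])
}

knownMetrics <- function(records) {
  sort(unique(unlist(lapply(records, function(r) {
    c(unlist(lapply(r$electrodeMetrics, names)),
      unlist(lapply(r$cellMetrics, names)),
      names(r$coloc))
  }))))
}

#' Aggregate a metric across cultures
#'
#' Two complementary analysis modes: `culture_based` first averages the
#' metric within each culture, then summarizes across culture means (each
#' culture contributes one value); `cell_based` pools every individual
#' value across cultures, representing within-culture variability. The two
#' coincide when every culture contributes exactly one value.
#'
#' @param records list of [cultureRecord()] objects.
#' @param metric metric name (e.g. `"burstiness"`, `"nJunctions"`, `"M1"`).
#' @param mode `"culture_based"` or `"cell_based"`.
#' @return a list of class `"AggregateSummary"`: `metric`, `mode`,
#'   `perCulture` (data.frame `cultureId`, `condition`, `div`, `mean`,
#'   `n`), and `overall` (data.frame `mean`, `sd`, `n`; for
#'   `culture_based`, `n` is the number of contributing cultures).
#' @examples
#' r1 <- cultureRecord("c1", "dissociated_2D", 14,
#'         cellMetrics = list(list(v = 1), list(v = 2), list(v = 3)))
#' r2 <- cultureRecord("c2", "aggregated_3D", 14,
#'         cellMetrics = list(list(v = 5), list(v = 7)))
#' aggregateMetrics(list(r1, r2), "v", "culture_based")$overall$mean  # 4
#' aggregateMetrics(list(r1, r2), "v", "cell_based")$overall$mean    # 3.6
#' @export
aggregateMetrics <- function(records, metric,
                             mode = c("culture_based", "cell_based")) {
  mode <- match.arg(mode)
  per <- lapply(records, function(r) {
    v <- metricValues(r, metric)
    data.frame(cultureId = r$cultureId, condition = r$condition,
               div = r$div,
               mean = if (length(v)) mean(v) else NA_real_,
               n = length(v))
  })
  per <- do.call(rbind, per)
  if (all(per$n == 0)) {
    stopf("metric '%s' not found on any record; available: %s", metric,
          paste(knownMetrics(records), collapse = ", "))
  }
  empty <- per$cultureId[per$n == 0]
  if (length(empty)) {
    warning("culture(s) with no values for '", metric, "' excluded: ",
            paste(empty, collapse = ", "))
  }
  overall <- if (mode == "culture_based") {
    cm <- per$mean[per$n > 0]
    data.frame(mean = mean(cm),
               sd = if (length(cm) > 1) stats::sd(cm) else NA_real_,
               n = length(cm))
  } else {
    pooled <- unlist(lapply(records, metricValues, metric = metric))
    data.frame(mean = mean(pooled),
               sd = if (length(pooled) > 1) stats::sd(pooled) else NA_real_,
               n = length(pooled))
  }
  structure(list(metric = metric, mode = mode, perCulture = per,
                 overall = overall),
            class = "AggregateSummary")
}
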
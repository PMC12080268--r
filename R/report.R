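# Stability reporting: combine per-variant measurements into a classified
# table plus a JSON-able summary (hit rates, correlations).

#' Build a stability report for a set of variants
#'
#' Joins per-variant melting temperatures, half-lives and fold activities,
#' computes delta Tm versus the wild type and a class label per metric
#' using [classify_vs_wt()], and summarizes hit rates and the
#' stability-activity correlation.
#'
#' @param records Data frame with columns `variant` and any of
#'   `tm`, `tm_sem`, `half_life`, `half_life_se`, `fold_activity`,
#'   `fold_sem`; must contain the wild-type row.
#' @param wt_name Wild-type label (default `"WT"`).
#' @param z_threshold Classification threshold (default 2).
#' @return List of class `"stability_report"` with `table` (per-variant
#'   rows incl. `delta_tm` and class labels) and `summary` (hit rates per
#'   metric and Spearman Tm-activity correlation when both present).
#' @export
stability_report <- function(records, wt_name = "WT", z_threshold = 2) {
  stopifnot("variant" %in% names(records), wt_name %in% records$variant)
  wt <- records[records$variant == wt_name, , drop = FALSE][1, ]
  tab <- records
  has <- function(col) col %in% names(records) && any(!is.na(records[[col]]))

  if (has("tm")) {
    dt <- t(vapply(seq_len(nrow(tab)), function(k) {
      delta_tm(tab$tm[k], tab$tm_sem[k], wt$tm, wt$tm_sem)
    }, numeric(2)))
    tab$delta_tm <- dt[, 1]
    tab$delta_tm_sem <- dt[, 2]
    tab$tm_class <- vapply(seq_len(nrow(tab)), function(k) {
      classify_vs_wt(tab$tm[k], tab$tm_sem[k], wt$tm, wt$tm_sem, z_threshold)
    }, character(1))
  }
  classify_col <- function(val, sem) {
    vapply(seq_len(nrow(tab)), function(k) {
      if (is.na(tab[[val]][k])) return(NA_character_)
      classify_vs_wt(tab[[val]][k], tab[[sem]][k], wt[[val]], wt[[sem]],
                     z_threshold)
    }, character(1))
  }
  if (has("half_life")) tab$half_life_class <- classify_col("half_life", "half_life_se")
  if (has("fold_activity")) tab$activity_class <- classify_col("fold_activity", "fold_sem")

  non_wt <- tab[tab$variant != wt_name, , drop = FALSE]
  rate <- function(cls) {
    cls <- cls[!is.na(cls)]
    if (!length(cls)) return(NA_real_)
    hit_rate(sum(cls == "improved"), length(cls))
  }
  summary <- list(n_variants = nrow(non_wt))
  if (has("tm")) summary$tm_hit_rate <- rate(non_wt$tm_class)
  if (has("half_life")) summary$half_life_hit_rate <- rate(non_wt$half_life_class)
  if (has("fold_activity")) summary$activity_hit_rate <- rate(non_wt$activity_class)
  if (has("tm") && has("fold_activity")) {
    ok <- !is.na(non_wt$tm) & !is.na(non_wt$fold_activity)
    if (sum(ok) >= 4)
      summary$spearman_tm_activity <-
        correlate_spearman(non_wt$tm[ok], non_wt$fold_activity[ok])[c("rho", "p_value")]
  }
  structure(list(table = tab, summary = summary), class = "stability_report")
}

#' Write a stability report to disk
#'
#' The per-variant table goes to tab-separated text, the summary to JSON.
#'
#' @param report A `"stability_report"`.
#' @param table_path,summary_path Output paths (skipped when `NULL`).
#' @return The report, invisibly.
#' @export
write_stability_report <- function(report, table_path = NULL, summary_path = NULL) {
  stopifnot(inherits(report, "stability_report"))
  if (!is.null(table_path))
    utils::write.table(report$table, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(summary_path))
    writeLines(jsonlite::toJSON(report$summary, digits = NA, auto_unbox = TRUE,
                                na = "null"), summary_path)
  invisible(report)
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report: ", x$summary$n_variants, " variants\n", sep = "")
  for (nm in setdiff(names(x$summary), "n_variants")) {
    val <- x$summary[[nm]]
    if (is.list(val)) val <- paste0("rho = ", round(val$rho, 2),
                                    ", p = ", signif(val$p_value, 2))
    else val <- round(val, 1)
    cat("  ", nm, ": ", val, "\n", sep = "")
  }
  invisible(x)
}
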
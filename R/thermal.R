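# Thermal-resistance characterization: plate-activity normalization,
# classification versus wild type, hit rates, delta Tm arithmetic,
# stability-activity correlation and experimental epistasis.

#' Normalize plate activities relative to the wild type
#'
#' Background-subtracts replicate signals (mean of the empty-vector wells
#' under the same condition) and divides each variant's mean net signal by
#' the wild type's, per condition. The SEM reflects the variant's replicate
#' variation only by default (ratio of means with variant-only SEM);
#' `propagate_wt = TRUE` adds the wild type's relative SEM in quadrature.
#' A variant whose replicates never exceed the background mean is flagged
#' inactive with fold 0.
#'
#' @param plate Data frame with columns `variant`, `condition`,
#'   `replicate`, `signal`, `is_background`.
#' @param wt_name Wild-type label (default `"WT"`).
#' @param propagate_wt Include WT uncertainty in the SEM (default FALSE).
#' @return Data frame with columns `variant`, `condition`, `fold_vs_wt`,
#'   `sem`, `n_replicates`, `inactive`.
#' @export
normalize_activity <- function(plate, wt_name = "WT", propagate_wt = FALSE) {
  need <- c("variant", "condition", "replicate", "signal", "is_background")
  if (!all(need %in% names(plate)))
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  if (any(plate$signal < 0)) stop("negative signals in plate table")
  out <- list()
  for (cond in unique(plate$condition)) {
    sub <- plate[plate$condition == cond, , drop = FALSE]
    bg <- sub$signal[sub$is_background]
    if (length(bg) == 0L) stop("no background (empty-vector) wells for condition ", cond)
    bg_mean <- mean(bg)
    fg <- sub[!sub$is_background, , drop = FALSE]
    if (!wt_name %in% fg$variant) stop("wild type '", wt_name, "' missing for condition ", cond)
    wt_sig <- fg$signal[fg$variant == wt_name]
    wt_net <- mean(wt_sig) - bg_mean
    if (wt_net <= 0) stop("wild-type signal does not exceed background for condition ", cond)
    wt_rel_sem <- sd(wt_sig) / sqrt(length(wt_sig)) / wt_net
    for (v in unique(fg$variant)) {
      sig <- fg$signal[fg$variant == v]
      net <- sig - bg_mean
      inactive <- all(sig <= bg_mean)
      fold <- mean(net) / wt_net
      sem <- sd(net) / sqrt(length(net)) / wt_net
      if (propagate_wt && v != wt_name)
        sem <- abs(fold) * sqrt((sem / max(abs(fold), .Machine$double.eps))^2 + wt_rel_sem^2)
      if (inactive) fold <- max(0, fold)
      out[[length(out) + 1L]] <- data.frame(
        variant = v, condition = cond, fold_vs_wt = fold,
        sem = if (length(sig) > 1L) sem else NA_real_,
        n_replicates = length(sig), inactive = inactive,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a measurement against the wild type
#'
#' Two-sample z rule on the combined SEM:
#' `z = (value - wt) / sqrt(sem^2 + wt_sem^2)`; `improved` if
#' `z >= z_threshold`, `reduced` if `z <= -z_threshold`, else `similar`.
#' With both SEMs zero the sign of the difference decides (equal values are
#' `similar`).
#'
#' @param value,sem Variant measurement and its SEM.
#' @param wt_value,wt_sem Wild-type measurement and its SEM.
#' @param z_threshold Significance threshold in combined-SEM units
#'   (default 2).
#' @return One of `"improved"`, `"similar"`, `"reduced"`.
#' @export
classify_vs_wt <- function(value, sem, wt_value, wt_sem, z_threshold = 2) {
  stopifnot(sem >= 0, wt_sem >= 0, z_threshold > 0)
  denom <- sqrt(sem^2 + wt_sem^2)
  if (denom == 0) {
    if (value == wt_value) return("similar")
    return(if (value > wt_value) "improved" else "reduced")
  }
  z <- (value - wt_value) / denom
  if (z >= z_threshold) "improved"
  else if (z <= -z_threshold) "reduced"
  else "similar"
}

#' Predictive hit rate
#'
#' `100 * n_improved / n_tested`, the percentage of tested predictions
#' classified as improved over the wild type.
#'
#' @param n_improved Number of improved variants.
#' @param n_tested Number of tested variants (> 0).
#' @return Percentage.
#' @export
hit_rate <- function(n_improved, n_tested) {
  stopifnot(n_tested > 0, n_improved >= 0, n_improved <= n_tested)
  100 * n_improved / n_tested
}

#' Melting-temperature difference versus wild type
#'
#' Difference of mean Tm values with the SEMs combined in quadrature,
#' rounded at the reporting precision (one decimal for temperatures).
#'
#' @param tm,tm_sem Variant melting temperature and SEM (deg C).
#' @param wt_tm,wt_tm_sem Wild-type melting temperature and SEM.
#' @param digits Rounding digits (default 1).
#' @return Named numeric vector `c(delta_tm, sem)`.
#' @export
delta_tm <- function(tm, tm_sem, wt_tm, wt_tm_sem, digits = 1) {
  if (is.na(tm) || is.na(wt_tm)) stop("missing Tm")
  c(delta_tm = round(tm - wt_tm, digits),
    sem = round(sqrt(tm_sem^2 + wt_tm_sem^2), digits))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; the two-sided p-value uses the t approximation
#' on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List with `rho`, `p_value`, `n`, and `flagged` (TRUE with a
#'   `reason` when either input is constant).
#' @export
correlate_spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                flagged = TRUE, reason = "constant input"))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       flagged = FALSE, reason = NA_character_)
}

#' Experimental epistasis of a double variant
#'
#' Deviation of the double variant's measured effect from the combination
#' of its constituent singles. Additive mode (for energies/temperatures):
#' `(double - wt) - [(a - wt) + (b - wt)]`. Multiplicative mode (for fold
#' changes): `double - a * b`. The sign reports positive/negative
#' epistasis.
#'
#' @param double_metric,single_a,single_b,wt Measurements (wt ignored in
#'   multiplicative mode, where inputs are fold changes vs wt).
#' @param mode `"additive"` or `"multiplicative"`.
#' @return List with `deviation` and `sign` (`"positive"`, `"negative"`,
#'   `"additive"` when zero).
#' @export
experimental_epistasis <- function(double_metric, single_a, single_b, wt = NULL,
                                   mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  if (mode == "additive") {
    if (is.null(wt) || is.na(wt)) stop("additive mode requires the wild-type measurement")
    if (anyNA(c(double_metric, single_a, single_b))) stop("missing measurement")
    dev <- (double_metric - wt) - ((single_a - wt) + (single_b - wt))
  } else {
    if (anyNA(c(double_metric, single_a, single_b))) stop("missing measurement")
    dev <- double_metric - single_a * single_b
  }
  sign_lab <- if (dev > 0) "positive" else if (dev < 0) "negative" else "additive"
  list(deviation = dev, sign = sign_lab)
}
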
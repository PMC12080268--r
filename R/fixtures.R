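# Machine-readable copies of the study's printed tables (single- and
# double-substitution predictions and measured melting temperatures) and a
# toy Potts model constructed to reproduce them, used by worked-example
# analyses and tests.

#' Load a packaged study table
#'
#' * `"T1"` — top 20 single-substitution predictions from the
#'   structure-based (ddG) and sequence-based (delta E) arms.
#' * `"T2"` — measured melting temperatures of the single-substituted
#'   variants and wild type, by prediction arm.
#' * `"T3"` — delta E and measured melting temperatures of the top 20
#'   double-substituted variants (wild type and best single as reference
#'   rows, flagged by `reference`).
#'
#' @param table_id `"T1"`, `"T2"` or `"T3"`.
#' @return Data frame with the printed rows.
#' @export
load_fixture <- function(table_id = c("T1", "T2", "T3")) {
  table_id <- match.arg(table_id)
  file <- switch(table_id,
                 T1 = "table1_single_predictions.csv",
                 T2 = "table2_single_tm.csv",
                 T3 = "table3_double_tm.csv")
  path <- system.file("extdata", file, package = "evstab", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Toy Potts model reproducing the fixture tables' delta E values
#'
#' Constructs a small model over the 16 positions covered by the
#' sequence-arm predictions: the local bias of each listed single mutation
#' is set to its printed delta E (all other substitutions are given a
#' strongly unfavorable bias), and a pair coupling is added for each listed
#' double so that its delta E matches the printed value. Scoring and
#' enumeration over this model therefore reproduce both tables exactly,
#' with the best single and best double ranked first.
#'
#' @param unfavorable Bias assigned to unlisted substitutions
#'   (default -50).
#' @return A `"potts_model"`.
#' @export
build_fixture_model <- function(unfavorable = -50) {
  t1 <- load_fixture("T1")
  t3 <- load_fixture("T3")
  singles <- lapply(t1$ev_variant, parse_variant)
  pos <- sort(unique(vapply(singles, function(v) v$pos, integer(1))))
  wt <- character(length(pos))
  for (v in singles) wt[match(v$pos, pos)] <- v$wt
  alpha <- aa_alphabet()
  L <- length(pos); q <- length(alpha)

  h <- matrix(unfavorable, L, q)
  h[, 1] <- 0  # gap state never enumerated; keep it neutral
  h[cbind(seq_len(L), match(wt, alpha))] <- 0
  for (k in seq_along(singles)) {
    v <- singles[[k]]
    h[match(v$pos, pos), match(v$mut, alpha)] <- t1$ev_delta_e[k]
  }

  J <- array(0, dim = c(L, L, q, q))
  single_de <- setNames(t1$ev_delta_e, t1$ev_variant)
  doubles <- t3[!t3$reference, , drop = FALSE]
  for (k in seq_len(nrow(doubles))) {
    v <- parse_variant(doubles$variant[k])
    parts <- strsplit(doubles$variant[k], "/", fixed = TRUE)[[1]]
    gap <- doubles$delta_e[k] - sum(single_de[parts])
    i <- match(v$pos[1], pos); j <- match(v$pos[2], pos)
    a <- match(v$mut[1], alpha); b <- match(v$mut[2], alpha)
    J[i, j, a, b] <- gap
    J[j, i, b, a] <- gap
  }
  potts_model(h = h, J = J, alphabet = alpha, focus_seq = wt,
              positions = pos, gauge = "none")
}

#' Expand the fixture ddG means and SEMs into per-run tables
#'
#' The structure-based predictions are reported as the mean and SEM of
#' five independent runs; this reconstructs, for each variant, five run
#' values with exactly that mean and SEM (a fixed centered, unit-SD
#' pattern scaled by `sem * sqrt(5)`), giving a deterministic synthetic
#' run table whose aggregation reproduces the printed values.
#'
#' @return Data frame with columns `variant`, `run`, `ddg`.
#' @export
fixture_ddg_runs <- function() {
  t1 <- load_fixture("T1")
  base <- c(-2, -1, 0, 1, 2)
  e <- base / sd(base)  # mean 0, sample SD 1
  out <- lapply(seq_len(nrow(t1)), function(k) {
    data.frame(variant = t1$foldx_variant[k], run = 1:5,
               ddg = t1$foldx_ddg[k] + t1$foldx_ddg_sem[k] * sqrt(5) * e,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
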
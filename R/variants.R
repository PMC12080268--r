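# Variant nomenclature, statistical-energy scoring (delta E), exhaustive
# single/double enumeration, epistasis decomposition, and ingestion of
# structure-based ddG run tables.

#' Parse a variant string
#'
#' Accepts the field's substitution nomenclature `"A123B"` for singles and
#' `"A123B/C456D"` for multi-substitution variants (1-based positions on
#' the ungapped focus sequence). Substitutions are sorted by position.
#'
#' @param name Variant string.
#' @return A list of class `"variant"` with `pos`, `wt`, `mut` (parallel
#'   vectors) and the canonical `name`.
#' @export
parse_variant <- function(name) {
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([A-Z])$", parts))
  if (any(lengths(m) != 4L))
    stop("cannot parse variant string: '", name, "'")
  wt <- vapply(m, `[`, character(1), 2L)
  pos <- as.integer(vapply(m, `[`, character(1), 3L))
  mut <- vapply(m, `[`, character(1), 4L)
  if (anyDuplicated(pos)) stop("variant '", name, "' repeats a position")
  if (any(wt == mut)) stop("variant '", name, "' has identical wild-type and mutant residue")
  aa20 <- setdiff(aa_alphabet(), "-")
  if (!all(mut %in% aa20)) stop("mutant residue outside the 20 amino acids in '", name, "'")
  o <- order(pos)
  v <- list(pos = pos[o], wt = wt[o], mut = mut[o])
  v$name <- format_variant(v)
  structure(v, class = "variant")
}

#' @rdname parse_variant
#' @param v A `"variant"` object (or a bare list with `pos`, `wt`, `mut`).
#' @export
format_variant <- function(v) {
  paste0(v$wt, v$pos, v$mut, collapse = "/")
}

.as_variant <- function(v) {
  if (inherits(v, "variant")) v else parse_variant(v)
}

.model_index <- function(model, pos) {
  idx <- match(pos, model$positions)
  if (anyNA(idx))
    stop("unmodeled position(s): ", paste(pos[is.na(idx)], collapse = ", "),
         " (filtered or outside the modeled sites)")
  idx
}

#' Statistical energy difference of a variant
#'
#' `delta E = E(variant) - E(wild type)` computed incrementally from only
#' the terms touching the substituted positions; exactly equal to the full
#' energy difference. Positive values indicate evolutionarily favored
#' variants.
#'
#' @param model A `"potts_model"`.
#' @param v A variant string or `"variant"` object; an empty substitution
#'   set (`NULL` or empty name) gives 0.
#' @return Scalar delta E.
#' @export
score_variant <- function(model, v) {
  stopifnot(inherits(model, "potts_model"))
  if (is.null(v) || (is.character(v) && length(v) == 1L && !nzchar(v))) return(0)
  v <- .as_variant(v)
  idx <- .model_index(model, v$pos)
  wt_states <- match(model$focus_seq, model$alphabet)
  bad <- model$focus_seq[idx] != v$wt
  if (any(bad))
    stop("wild-type mismatch at position(s) ",
         paste(v$pos[bad], collapse = ", "), ": model has ",
         paste(model$focus_seq[idx][bad], collapse = ", "))
  mut_states <- match(v$mut, model$alphabet)
  de <- 0
  L <- model$L
  k <- length(idx)
  for (a in seq_len(k)) {
    i <- idx[a]
    de <- de + model$h[i, mut_states[a]] - model$h[i, wt_states[i]]
    js <- setdiff(seq_len(L), idx)
    if (length(js)) {
      de <- de + sum(model$J[cbind(i, js, mut_states[a], wt_states[js])]) -
                 sum(model$J[cbind(i, js, wt_states[i], wt_states[js])])
    }
  }
  if (k >= 2L) {
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        i <- idx[a]; j <- idx[b]
        de <- de + model$J[i, j, mut_states[a], mut_states[b]] -
                   model$J[i, j, wt_states[i], wt_states[j]]
      }
    }
  }
  de
}

#' Enumerate and rank variants by statistical energy
#'
#' Enumerates all single substitutions (every modeled position, 19 non-wild-
#' type amino acids; the gap state is never proposed) or all double
#' substitutions (every unordered position pair, 19 x 19 combinations),
#' scores them by delta E, and returns the `top_k` in decreasing order.
#' Ties are broken by position and then mutant residue, so the ranking is a
#' total order.
#'
#' @param model A `"potts_model"`.
#' @param order `"single"` or `"double"`.
#' @param top_k Number of top variants to return (all, with a warning, if
#'   larger than the enumeration).
#' @return Data frame with columns `rank`, `variant`, `delta_e`.
#' @export
enumerate_and_rank <- function(model, order = c("single", "double"), top_k = 20L) {
  stopifnot(inherits(model, "potts_model"), top_k >= 1)
  order <- match.arg(order)
  L <- model$L
  alpha <- model$alphabet
  aa20 <- setdiff(alpha, "-")
  wt_states <- match(model$focus_seq, alpha)

  # single delta E for every (site, mutant residue): h term + couplings to
  # the wild-type background
  mut_states <- match(aa20, alpha)
  single_de <- matrix(NA_real_, L, length(aa20),
                      dimnames = list(NULL, aa20))
  for (i in seq_len(L)) {
    js <- setdiff(seq_len(L), i)
    base <- model$h[i, wt_states[i]] +
      if (length(js)) sum(model$J[cbind(i, js, wt_states[i], wt_states[js])]) else 0
    for (m in seq_along(aa20)) {
      a <- mut_states[m]
      val <- model$h[i, a] +
        if (length(js)) sum(model$J[cbind(i, js, a, wt_states[js])]) else 0
      single_de[i, m] <- val - base
    }
  }

  if (order == "single") {
    rows <- expand.grid(i = seq_len(L), m = seq_along(aa20))
    keep <- aa20[rows$m] != model$focus_seq[rows$i]
    rows <- rows[keep, , drop = FALSE]
    tab <- data.frame(
      pos1 = model$positions[rows$i],
      mut1 = aa20[rows$m],
      variant = paste0(model$focus_seq[rows$i], model$positions[rows$i], aa20[rows$m]),
      delta_e = single_de[cbind(rows$i, rows$m)],
      stringsAsFactors = FALSE)
    tab <- tab[base::order(-tab$delta_e, tab$pos1, tab$mut1), , drop = FALSE]
  } else {
    out <- vector("list", L * (L - 1L) / 2L)
    k <- 0L
    for (i in seq_len(L - 1L)) {
      for (j in (i + 1L):L) {
        mi <- which(aa20 != model$focus_seq[i])
        mj <- which(aa20 != model$focus_seq[j])
        gap <- matrix(model$J[i, j, mut_states[mi], mut_states[mj]],
                      length(mi), length(mj)) -
          outer(model$J[i, j, mut_states[mi], wt_states[j]], rep(1, length(mj))) -
          outer(rep(1, length(mi)), model$J[i, j, wt_states[i], mut_states[mj]]) +
          model$J[i, j, wt_states[i], wt_states[j]]
        de <- outer(single_de[i, mi], single_de[j, mj], "+") + gap
        grid <- expand.grid(a = seq_along(mi), b = seq_along(mj))
        k <- k + 1L
        out[[k]] <- data.frame(
          pos1 = model$positions[i], mut1 = aa20[mi][grid$a],
          pos2 = model$positions[j], mut2 = aa20[mj][grid$b],
          variant = paste0(model$focus_seq[i], model$positions[i], aa20[mi][grid$a],
                           "/", model$focus_seq[j], model$positions[j], aa20[mj][grid$b]),
          delta_e = de[cbind(grid$a, grid$b)],
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, out)
    tab <- tab[base::order(-tab$delta_e, tab$pos1, tab$mut1, tab$pos2, tab$mut2), ,
               drop = FALSE]
  }
  if (top_k > nrow(tab)) {
    warning("top_k = ", top_k, " exceeds the enumeration size (", nrow(tab),
            "); returning all variants")
    top_k <- nrow(tab)
  }
  tab <- tab[seq_len(top_k), c("variant", "delta_e"), drop = FALSE]
  rownames(tab) <- NULL
  cbind(rank = seq_len(top_k), tab)
}

#' Decompose a double variant's delta E into single effects and coupling
#'
#' `coupling_gap = delta_e_double - delta_e_a - delta_e_b`. Computed from a
#' model, the gap equals the four-term coupling difference
#' `J(a', b') - J(a', b) - J(a, b') + J(a, b)` at the substituted pair.
#' Alternatively a pre-computed score table (columns `variant`, `delta_e`)
#' can supply the three scores.
#'
#' @param model A `"potts_model"`, or `NULL` when `score_table` is given.
#' @param double A double-substitution variant string or `"variant"`.
#' @param score_table Optional data frame with columns `variant`, `delta_e`.
#' @return A list of class `"epistasis_record"` with `double`,
#'   `delta_e_double`, `delta_e_a`, `delta_e_b`, `coupling_gap`.
#' @export
epistasis_decompose <- function(model = NULL, double, score_table = NULL) {
  v <- .as_variant(double)
  if (length(v$pos) != 2L) stop("epistasis decomposition requires a double variant")
  a <- list(pos = v$pos[1], wt = v$wt[1], mut = v$mut[1])
  b <- list(pos = v$pos[2], wt = v$wt[2], mut = v$mut[2])
  a$name <- format_variant(a); b$name <- format_variant(b)
  if (!is.null(model)) {
    de_ab <- score_variant(model, v)
    de_a <- score_variant(model, a$name)
    de_b <- score_variant(model, b$name)
  } else {
    if (is.null(score_table)) stop("either a model or a score table is required")
    lookup <- function(nm) {
      i <- match(nm, score_table$variant)
      if (is.na(i)) stop("missing constituent score for ", nm)
      score_table$delta_e[i]
    }
    de_ab <- lookup(v$name); de_a <- lookup(a$name); de_b <- lookup(b$name)
  }
  structure(list(double = v$name, delta_e_double = de_ab,
                 delta_e_a = de_a, delta_e_b = de_b,
                 coupling_gap = de_ab - de_a - de_b),
            class = "epistasis_record")
}

#' @export
print.epistasis_record <- function(x, ...) {
  cat(x$double, ": dE = ", format(x$delta_e_double, digits = 4),
      " = ", format(x$delta_e_a, digits = 4), " + ",
      format(x$delta_e_b, digits = 4), " + gap ",
      format(x$coupling_gap, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Aggregate ddG run tables into ranked variant scores
#'
#' Structure-based stability predictions arrive as several independent runs
#' per variant; this computes the per-variant mean and SEM (sample standard
#' deviation / sqrt(runs)) and ranks variants ascending by mean ddG, so the
#' most stabilizing (most negative) comes first. Ties are broken by variant
#' name.
#'
#' @param runs Data frame with columns `variant`, `run` (run index) and
#'   `ddg` (kcal/mol), or a path to a delimited file with those columns.
#' @param stabilizing_only Keep only variants with mean ddG < 0
#'   (default FALSE).
#' @return Data frame with columns `rank`, `variant`, `ddg_mean`,
#'   `ddg_sem`, `n_runs`, `stabilizing`.
#' @export
ingest_ddg_runs <- function(runs, stabilizing_only = FALSE) {
  if (is.character(runs)) runs <- read.csv(runs, stringsAsFactors = FALSE)
  need <- c("variant", "run", "ddg")
  if (!all(need %in% names(runs)))
    stop("ddG run table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(runs$ddg)) stop("non-numeric ddg values")
  if (anyNA(runs$ddg)) stop("missing ddg values")
  if (anyDuplicated(runs[c("variant", "run")]))
    stop("duplicate (variant, run) entries")
  sp <- split(runs$ddg, runs$variant)
  agg <- data.frame(
    variant = names(sp),
    ddg_mean = vapply(sp, mean, numeric(1)),
    ddg_sem = vapply(sp, function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0,
                     numeric(1)),
    n_runs = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE)
  agg <- agg[base::order(agg$ddg_mean, agg$variant), , drop = FALSE]
  if (stabilizing_only) agg <- agg[agg$ddg_mean < 0, , drop = FALSE]
  agg$stabilizing <- agg$ddg_mean < 0
  rownames(agg) <- NULL
  cbind(rank = seq_len(nrow(agg)), agg)
}

#' Write a variant score table as delimited text
#'
#' @param scores Data frame from [enumerate_and_rank()] or
#'   [ingest_ddg_runs()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
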
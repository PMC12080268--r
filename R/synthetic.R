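# Synthetic-data generators with known ground truth. Every generator is
# deterministic given its parameters and seed, and attaches a
# "synthetic_truth" attribute recording them; pipeline stages never read
# the truth (blind analysis), only tests and recovery checks do.

.with_truth <- function(x, generator, params, seed) {
  attr(x, "synthetic_truth") <- list(generator = generator, params = params,
                                     seed = seed)
  x
}

#' Ground-truth record of a synthetic dataset
#'
#' @param x An object produced by one of the generators.
#' @return List with `generator`, `params`, `seed`.
#' @export
synthetic_truth <- function(x) {
  tr <- attr(x, "synthetic_truth")
  if (is.null(tr)) stop("object carries no synthetic truth")
  tr
}

#' Write / read a synthetic-truth record as JSON
#'
#' @param x A generated object (or a truth list).
#' @param path JSON path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the list.
#' @export
write_truth <- function(x, path) {
  tr <- if (is.list(x) && !is.null(x$generator)) x else synthetic_truth(x)
  writeLines(jsonlite::toJSON(tr, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::fromJSON(path)

#' Sample an alignment from a Potts model by Gibbs sampling
#'
#' Single-site Gibbs updates with exact conditional distributions
#' `p(sigma_i = a | sigma_-i) propto exp(h_i(a) + sum_j J_ij(a, sigma_j))`.
#' One sweep updates every site once in order. The chain starts from the
#' model's focus sequence, discards `burn_in` sweeps and records a sequence
#' every `thin` sweeps. The returned alignment carries the focus (wild
#' type) sequence as its first row.
#'
#' @param model A `"potts_model"`.
#' @param n_sequences Number of sampled sequences (>= 1).
#' @param burn_in Burn-in sweeps (default 100).
#' @param thin Sweeps between recorded samples (default 5).
#' @param seed Random seed.
#' @return An `"msa"` object with `n_sequences + 1` rows (focus first).
#' @export
sample_msa <- function(model, n_sequences, burn_in = 100L, thin = 5L, seed = 1L) {
  stopifnot(inherits(model, "potts_model"),
            n_sequences >= 1, burn_in >= 1, thin >= 1)
  set.seed(seed)
  L <- model$L; q <- model$q
  state <- match(model$focus_seq, model$alphabet)
  sweep_once <- function(state) {
    for (i in seq_len(L)) {
      logit <- model$h[i, ]
      js <- setdiff(seq_len(L), i)
      for (j in js) logit <- logit + model$J[i, j, , state[j]]
      p <- exp(logit - max(logit))
      state[i] <- sample.int(q, 1L, prob = p)
    }
    state
  }
  for (s in seq_len(burn_in)) state <- sweep_once(state)
  samples <- matrix(NA_integer_, n_sequences, L)
  for (m in seq_len(n_sequences)) {
    for (s in seq_len(thin)) state <- sweep_once(state)
    samples[m, ] <- state
  }
  mat <- rbind(model$focus_seq,
               matrix(model$alphabet[samples], n_sequences, L))
  aln <- msa_from_matrix(mat,
                         ids = c("focus", paste0("sample_", seq_len(n_sequences))),
                         focus_id = "focus",
                         column_map = model$positions,
                         alphabet = model$alphabet)
  .with_truth(aln, "sample_msa",
              list(L = L, q = q, n_sequences = n_sequences,
                   burn_in = burn_in, thin = thin), seed)
}

#' Generate a two-state thermal unfolding curve
#'
#' Signal = linear pre-transition baseline mixed with the post-transition
#' baseline through the two-state logistic
#' `f(T) = 1 / (1 + exp((tm - T) / slope))`, plus additive Gaussian noise
#' (instrument-like behavior for scanning-fluorimetry traces).
#'
#' @param tm True melting temperature (deg C), inside the grid.
#' @param slope Transition width parameter (deg C, default 2).
#' @param baselines Named list/vector with `pre`, `post` (levels at the
#'   transition midpoint) and `pre_slope`, `post_slope` (per deg C).
#' @param noise_sd Additive Gaussian noise SD in signal units.
#' @param grid Temperature grid (default 20-95 deg C at 1 deg C, the usual
#'   1 deg C/min ramp read once per minute).
#' @param seed Random seed.
#' @return A `"melting_curve"` data frame with columns `temperature`,
#'   `signal` and a truth attribute.
#' @export
make_melting_curve <- function(tm, slope = 2,
                               baselines = list(pre = 0.85, post = 1.05,
                                                pre_slope = 5e-4, post_slope = 5e-4),
                               noise_sd = 0, grid = seq(20, 95, by = 1),
                               seed = 1L) {
  if (tm < min(grid) || tm > max(grid)) stop("tm outside the temperature grid")
  set.seed(seed)
  f <- 1 / (1 + exp((tm - grid) / slope))
  pre <- baselines$pre + baselines$pre_slope * (grid - tm)
  post <- baselines$post + baselines$post_slope * (grid - tm)
  signal <- pre * (1 - f) + post * f + rnorm(length(grid), 0, noise_sd)
  curve <- data.frame(temperature = grid, signal = signal)
  class(curve) <- c("melting_curve", "data.frame")
  .with_truth(curve, "make_melting_curve",
              list(tm = tm, slope = slope, baselines = baselines,
                   noise_sd = noise_sd,
                   amplitude = abs(baselines$post - baselines$pre)), seed)
}

#' Generate a first-order activity-decay time course
#'
#' Replicate residual activities
#' `a0 * exp(-ln 2 * t / t_half) * (1 + N(0, noise_frac))`, clipped at 0
#' (multiplicative, CV-style assay noise).
#'
#' @param t_half True half-life (minutes, > 0).
#' @param a0 Activity at t = 0 (default 100).
#' @param times Sampling times in minutes (default every 15 min over
#'   0-150 min).
#' @param n_replicates Replicates per time point (default 3).
#' @param noise_frac Coefficient of variation of the noise (default 0).
#' @param seed Random seed.
#' @return A `"decay_series"` data frame with columns `time`, `replicate`,
#'   `activity` and a truth attribute.
#' @export
make_decay_series <- function(t_half, a0 = 100, times = seq(0, 150, by = 15),
                              n_replicates = 3L, noise_frac = 0, seed = 1L) {
  stopifnot(t_half > 0, n_replicates >= 1)
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_replicates), time = times)
  mu <- a0 * exp(-log(2) * grid$time / t_half)
  act <- pmax(0, mu * (1 + rnorm(nrow(grid), 0, noise_frac)))
  series <- data.frame(time = grid$time, replicate = grid$replicate,
                       activity = act)
  class(series) <- c("decay_series", "data.frame")
  .with_truth(series, "make_decay_series",
              list(t_half = t_half, a0 = a0, times = times,
                   n_replicates = n_replicates, noise_frac = noise_frac),
              seed)
}

#' Generate a replicated assay plate with known fold changes
#'
#' Each variant's true signal is
#' `background + fold * (wt_signal - background)`; replicates (and
#' empty-vector background wells) get multiplicative Gaussian noise. The
#' wild type is included with fold 1 under the name `"WT"`.
#'
#' @param true_folds Named numeric vector mapping variant names to true
#'   fold changes (>= 0).
#' @param wt_signal True wild-type signal (> background).
#' @param background True empty-vector signal.
#' @param n_replicates Replicates per variant and background wells
#'   (default 3).
#' @param noise_frac Coefficient of variation of the noise (default 0).
#' @param condition Condition label (default `"T60"`).
#' @param seed Random seed.
#' @return A plate data frame (`variant`, `condition`, `replicate`,
#'   `signal`, `is_background`) with a truth attribute.
#' @export
make_plate <- function(true_folds, wt_signal = 1.0, background = 0.1,
                       n_replicates = 3L, noise_frac = 0,
                       condition = "T60", seed = 1L) {
  stopifnot(all(true_folds >= 0), wt_signal > background, background >= 0)
  set.seed(seed)
  folds <- c(WT = 1, true_folds[setdiff(names(true_folds), "WT")])
  rows <- list()
  for (v in names(folds)) {
    mu <- background + folds[[v]] * (wt_signal - background)
    sig <- pmax(0, mu * (1 + rnorm(n_replicates, 0, noise_frac)))
    rows[[length(rows) + 1L]] <- data.frame(
      variant = v, condition = condition, replicate = seq_len(n_replicates),
      signal = sig, is_background = FALSE, stringsAsFactors = FALSE)
  }
  bg <- pmax(0, background * (1 + rnorm(n_replicates, 0, noise_frac)))
  rows[[length(rows) + 1L]] <- data.frame(
    variant = "empty_vector", condition = condition,
    replicate = seq_len(n_replicates), signal = bg, is_background = TRUE,
    stringsAsFactors = FALSE)
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  .with_truth(plate, "make_plate",
              list(true_folds = as.list(folds), wt_signal = wt_signal,
                   background = background, n_replicates = n_replicates,
                   noise_frac = noise_frac, condition = condition), seed)
}
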
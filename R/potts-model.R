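# Potts (DCA) sequence model: local biases h_i(a) and pairwise couplings
# J_ij(a, b). The statistical energy of a sequence is
#   E(sigma) = sum_i h_i(sigma_i) + sum_{i<j} J_ij(sigma_i, sigma_j),
# with the sign convention that HIGHER energy is more favorable, so
# beneficial variants have positive delta E relative to the wild type.

MODEL_FORMAT <- "evstab-potts"
MODEL_VERSION <- 1L

#' Construct a Potts model
#'
#' @param h L x q matrix of local biases.
#' @param J L x L x q x q array of couplings, with
#'   `J[i, j, a, b] == J[j, i, b, a]` and a zero diagonal. `NULL` gives an
#'   all-zero coupling tensor (independent-site model).
#' @param alphabet State alphabet (gap first if present); `q = length(alphabet)`.
#' @param focus_seq Wild-type sequence over the modeled positions
#'   (character vector of length L, no gap state).
#' @param positions 1-based positions of the modeled sites on the ungapped
#'   focus sequence (default `1:L`); used to map variant coordinates.
#' @param lambda_h,lambda_e Regularization strengths recorded with the
#'   model (metadata; `NA` for hand-built models).
#' @param gauge Gauge label, e.g. `"none"` or `"zero-sum"`.
#' @return An object of class `"potts_model"`.
#' @export
potts_model <- function(h, J = NULL, alphabet, focus_seq,
                        positions = NULL, lambda_h = NA_real_,
                        lambda_e = NA_real_, gauge = "none") {
  L <- nrow(h)
  q <- ncol(h)
  stopifnot(length(alphabet) == q, length(focus_seq) == L)
  if (is.null(J)) J <- array(0, dim = c(L, L, q, q))
  stopifnot(all(dim(J) == c(L, L, q, q)))
  if (is.null(positions)) positions <- seq_len(L)
  stopifnot(length(positions) == L, !is.unsorted(positions, strictly = TRUE))
  if (any(focus_seq == "-")) stop("focus_seq must not contain the gap state")
  if (!all(focus_seq %in% alphabet)) stop("focus_seq contains states outside the alphabet")
  structure(list(L = L, q = q, h = h, J = J, alphabet = alphabet,
                 focus_seq = focus_seq, positions = as.integer(positions),
                 lambda_h = lambda_h, lambda_e = lambda_e, gauge = gauge),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat("Potts model: L = ", x$L, ", q = ", x$q, ", gauge = ", x$gauge, "\n", sep = "")
  cat("lambda_h = ", x$lambda_h, ", lambda_e = ", x$lambda_e, "\n", sep = "")
  invisible(x)
}

.encode_seq <- function(model, sigma) {
  if (is.character(sigma) && length(sigma) == 1L && nchar(sigma) > 1L)
    sigma <- strsplit(sigma, "")[[1]]
  if (is.character(sigma)) {
    idx <- match(sigma, model$alphabet)
    if (anyNA(idx))
      stop("unknown state(s): ", paste(unique(sigma[is.na(idx)]), collapse = ", "))
    sigma <- idx
  }
  if (length(sigma) != model$L)
    stop("sequence length ", length(sigma), " does not match model L = ", model$L)
  as.integer(sigma)
}

#' Statistical energy of a sequence under a Potts model
#'
#' `E(sigma) = sum_i h_i(sigma_i) + sum_{i<j} J_ij(sigma_i, sigma_j)`.
#' Higher energies are more favorable.
#'
#' @param model A `"potts_model"`.
#' @param sigma Sequence over the model's alphabet: a character vector of
#'   length L, a single string, or integer state indices.
#' @return Scalar statistical energy.
#' @export
energy <- function(model, sigma) {
  stopifnot(inherits(model, "potts_model"))
  s <- .encode_seq(model, sigma)
  L <- model$L
  e <- sum(model$h[cbind(seq_len(L), s)])
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) {
      j <- (i + 1L):L
      e <- e + sum(model$J[cbind(i, j, s[i], s[j])])
    }
  }
  e
}

#' Convert a Potts model to the zero-sum gauge
#'
#' Fixes the gauge freedom of the pairwise model so that
#' `sum_a h_i(a) = 0` and `sum_a J_ij(a, b) = 0` for every i, j, b, while
#' preserving every energy difference `E(sigma) - E(tau)`.
#'
#' @param model A `"potts_model"`.
#' @return The gauge-fixed `"potts_model"` (`gauge = "zero-sum"`).
#' @export
to_zero_sum_gauge <- function(model) {
  stopifnot(inherits(model, "potts_model"))
  L <- model$L; q <- model$q
  h <- model$h
  J <- model$J
  Jz <- array(0, dim = dim(J))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      K <- J[i, j, , ]
      rm_ <- rowMeans(K); cm_ <- colMeans(K); mm <- mean(K)
      Jz[i, j, , ] <- K - outer(rm_, rep(1, q)) - outer(rep(1, q), cm_) + mm
      # row means of K shift into h_i; the double mean is a constant
      h[i, ] <- h[i, ] + (rm_ - mm)
    }
  }
  h <- h - rowMeans(h)
  potts_model(h = h, J = Jz, alphabet = model$alphabet,
              focus_seq = model$focus_seq, positions = model$positions,
              lambda_h = model$lambda_h, lambda_e = model$lambda_e,
              gauge = "zero-sum")
}

#' Save / load a Potts model
#'
#' The model is serialized to a versioned JSON container holding the named
#' arrays `h` and `J`, the alphabet, focus sequence, positions and
#' regularization metadata. Round trips are lossless (17 significant
#' digits, exact for IEEE doubles).
#'
#' @param model A `"potts_model"`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "potts_model"))
  payload <- list(
    format = MODEL_FORMAT, version = MODEL_VERSION,
    L = model$L, q = model$q,
    alphabet = model$alphabet, focus_seq = model$focus_seq,
    positions = model$positions,
    lambda_h = model$lambda_h, lambda_e = model$lambda_e,
    gauge = model$gauge,
    # 17 significant digits round-trip IEEE doubles exactly
    h = sprintf("%.17g", as.vector(model$h)),
    J = sprintf("%.17g", as.vector(model$J))
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              na = "string"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e) stop("not a valid model file: ", conditionMessage(e)))
  if (is.null(payload$format) || !identical(payload$format, MODEL_FORMAT))
    stop("model file format error: missing or unexpected format tag")
  if (!identical(as.integer(payload$version), MODEL_VERSION))
    stop("model file version mismatch: got ", payload$version,
         ", expected ", MODEL_VERSION)
  L <- payload$L; q <- payload$q
  if (length(payload$h) != L * q || length(payload$J) != (L * q)^2)
    stop("model file truncated: array lengths do not match header dimensions")
  lam_h <- suppressWarnings(as.numeric(payload$lambda_h))
  lam_e <- suppressWarnings(as.numeric(payload$lambda_e))
  potts_model(h = matrix(as.numeric(payload$h), L, q),
              J = array(as.numeric(payload$J), dim = c(L, L, q, q)),
              alphabet = payload$alphabet, focus_seq = payload$focus_seq,
              positions = payload$positions,
              lambda_h = lam_h, lambda_e = lam_e, gauge = payload$gauge)
}
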
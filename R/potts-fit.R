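# Regularized pseudo-likelihood maximization (PLM) for Potts models.
#
# Each site's conditional likelihood p(sigma_i | sigma_{-i}) is maximized
# independently over (h_i, J_i.) with L2 penalties, and the asymmetric
# coupling estimates are symmetrized by averaging J_ij and J_ji. The
# weighted log-likelihood is normalized by the total sequence weight, so
# the fit is invariant to rescaling all weights (and hence to duplicating
# the alignment when weights are recomputed); the lambda penalties act on
# that normalized objective. The fitted model is returned in the zero-sum
# gauge.

#' Coupling regularization under the "auto" rule
#'
#' Resolves `lambda_e = 0.2 * (L - 1)` where L is the number of modeled
#' sites, the convention used for plmc-style coupling penalties.
#'
#' @param L Number of modeled sites.
#' @return The coupling L2 strength.
#' @export
auto_lambda_e <- function(L) 0.2 * (L - 1)

#' Fit a Potts model by pseudo-likelihood maximization
#'
#' @param aln An `"msa"` object (the gap state is modeled).
#' @param w A `"seq_weights"` object, or `NULL` for uniform weights.
#' @param lambda_h L2 strength on local biases (default 0.01).
#' @param lambda_e L2 strength on couplings; `"auto"` resolves
#'   `0.2 * (L - 1)` (see [auto_lambda_e()]).
#' @param tol Projected-gradient tolerance for the quasi-Newton optimizer
#'   (default 1e-5).
#' @param max_iter Maximum optimizer iterations per site (default 500).
#' @param seed Seed recorded in the report. Initialization is at zero, so
#'   the fit is deterministic; the seed is retained for future stochastic
#'   initializations.
#' @return A list with `model` (a zero-sum-gauge `"potts_model"`) and
#'   `report` (a `"plm_fit_report"`: iterations, objective, gradient norm,
#'   convergence flag, n_eff, lambdas, seed, and the lambda scaling
#'   convention).
#' @export
fit_plm <- function(aln, w = NULL, lambda_h = 0.01, lambda_e = "auto",
                    tol = 1e-5, max_iter = 500L, seed = 0L) {
  stopifnot(inherits(aln, "msa"))
  mat <- aln$matrix
  n <- nrow(mat); L <- ncol(mat)
  if (n == 0L) stop("empty alignment")
  if (L < 2L) stop("PLM requires at least 2 modeled sites (L >= 2)")
  q <- length(aln$alphabet)
  if (identical(lambda_e, "auto")) lambda_e <- auto_lambda_e(L)
  stopifnot(lambda_h > 0, lambda_e >= 0)

  weights <- if (is.null(w)) rep(1, n) else w$weights
  stopifnot(length(weights) == n)
  wn <- weights / sum(weights)
  n_eff <- sum(weights)
  enc <- matrix(match(mat, aln$alphabet), nrow = n)
  if (anyNA(enc)) stop("alignment contains states outside its alphabet")

  onehot <- lapply(seq_len(L), function(j) {
    M <- matrix(0, n, q)
    M[cbind(seq_len(n), enc[, j])] <- 1
    M
  })

  h <- matrix(0, L, q)
  J <- array(0, dim = c(L, L, q, q))
  tot_iter <- 0L
  tot_obj <- 0
  max_gnorm <- 0
  all_conv <- TRUE

  for (i in seq_len(L)) {
    others <- setdiff(seq_len(L), i)
    xi <- enc[, i]
    npar <- q + length(others) * q * q

    unpack <- function(theta) {
      hi <- theta[seq_len(q)]
      Ji <- array(theta[-seq_len(q)], dim = c(q, q, length(others)))
      list(hi = hi, Ji = Ji)
    }
    logits_of <- function(p) {
      lg <- matrix(p$hi, q, n)
      for (k in seq_along(others)) {
        lg <- lg + p$Ji[, enc[, others[k]], k]
      }
      lg
    }
    objgrad <- function(theta, want_grad = TRUE) {
      p <- unpack(theta)
      lg <- logits_of(p)
      m <- apply(lg, 2, max)
      lse <- m + log(colSums(exp(sweep(lg, 2, m))))
      nll <- -sum(wn * (lg[cbind(xi, seq_len(n))] - lse))
      obj <- nll + lambda_h * sum(p$hi^2) + (lambda_e / 2) * sum(p$Ji^2)
      if (!want_grad) return(list(obj = obj))
      P <- exp(sweep(lg, 2, lse))            # q x n conditional probabilities
      D <- sweep(P - t(onehot[[i]]), 2, wn, "*")
      g_h <- rowSums(D) + 2 * lambda_h * p$hi
      g_J <- array(0, dim = dim(p$Ji))
      for (k in seq_along(others)) {
        g_J[, , k] <- D %*% onehot[[others[k]]] + lambda_e * p$Ji[, , k]
      }
      list(obj = obj, grad = c(g_h, as.vector(g_J)))
    }

    fit <- optim(par = numeric(npar),
                 fn = function(th) objgrad(th, want_grad = FALSE)$obj,
                 gr = function(th) objgrad(th)$grad,
                 method = "L-BFGS-B",
                 control = list(maxit = max_iter, pgtol = tol, factr = 1e5))
    gnorm <- max(abs(objgrad(fit$par)$grad))
    p <- unpack(fit$par)
    h[i, ] <- p$hi
    for (k in seq_along(others)) {
      J[i, others[k], , ] <- p$Ji[, , k]
    }
    tot_iter <- tot_iter + fit$counts[["function"]]
    tot_obj <- tot_obj + fit$value
    max_gnorm <- max(max_gnorm, gnorm)
    all_conv <- all_conv && (fit$convergence == 0L)
  }

  # symmetrize the asymmetric per-site estimates
  Jsym <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      K <- (J[i, j, , ] + t(J[j, i, , ])) / 2
      Jsym[i, j, , ] <- K
      Jsym[j, i, , ] <- t(K)
    }
  }

  focus_row <- aln$matrix[match(aln$focus_id, aln$ids), ]
  model <- potts_model(h = h, J = Jsym, alphabet = aln$alphabet,
                       focus_seq = focus_row, positions = aln$column_map,
                       lambda_h = lambda_h, lambda_e = lambda_e,
                       gauge = "none")
  model <- to_zero_sum_gauge(model)
  report <- structure(list(
    n_iterations = tot_iter, final_objective = tot_obj,
    gradient_norm = max_gnorm, converged = all_conv,
    n_eff = n_eff, lambda_h = lambda_h, lambda_e = lambda_e, seed = seed,
    lambda_scaling = "penalties on the weight-normalized (mean) pseudo-log-likelihood; invariant to rescaling all weights"),
    class = "plm_fit_report")
  list(model = model, report = report)
}

#' @export
print.plm_fit_report <- function(x, ...) {
  cat("PLM fit: ", x$n_iterations, " objective evaluations, objective = ",
      format(x$final_objective, digits = 6), "\n", sep = "")
  cat("max |grad| = ", format(x$gradient_norm, digits = 3),
      ", converged = ", x$converged, ", n_eff = ",
      format(x$n_eff, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Per-pair coupling strengths (Frobenius norms)
#'
#' Frobenius norm of each gauge-fixed coupling matrix, the standard summary
#' of direct-coupling strength between two sites.
#'
#' @param model A `"potts_model"` (converted to zero-sum gauge first unless
#'   already in it).
#' @param gap_excluded Drop the gap state before computing norms
#'   (default FALSE).
#' @return Data frame with columns `i`, `j` (modeled positions, 1-based
#'   focus coordinates) and `fn` (Frobenius norm), sorted decreasing.
#' @export
coupling_norms <- function(model, gap_excluded = FALSE) {
  stopifnot(inherits(model, "potts_model"))
  if (!identical(model$gauge, "zero-sum")) model <- to_zero_sum_gauge(model)
  L <- model$L
  states <- seq_len(model$q)
  if (gap_excluded && "-" %in% model$alphabet)
    states <- states[model$alphabet != "-"]
  out <- list()
  k <- 0L
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      k <- k + 1L
      out[[k]] <- data.frame(i = model$positions[i], j = model$positions[j],
                             fn = sqrt(sum(model$J[i, j, states, states]^2)))
    }
  }
  res <- do.call(rbind, out)
  res[order(-res$fn), , drop = FALSE]
}
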
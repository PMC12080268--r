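# Sequence reweighting and weighted frequency statistics.
#
# Reweighting follows the standard DCA convention: each sequence is
# down-weighted by the size of its identity cluster, so the effective
# sample size n_eff reflects sequence diversity rather than database
# redundancy.

#' Identity-based sequence weights
#'
#' The weight of sequence s is `1 / |{t : identity(s, t) >= 1 - theta}|`,
#' counting s itself, where identity is the fraction of alignment columns
#' (gaps included) at which two rows agree. `n_eff` is the sum of weights.
#'
#' @param aln An `"msa"` object.
#' @param theta Identity-clustering threshold as a fractional distance
#'   (default 0.2, i.e. 80\% identity clustering).
#' @return A list of class `"seq_weights"` with `weights`, `theta`, `n_eff`.
#' @export
compute_weights <- function(aln, theta = 0.2) {
  stopifnot(inherits(aln, "msa"), theta >= 0, theta < 1)
  mat <- aln$matrix
  n <- nrow(mat)
  if (n == 0L) stop("empty alignment")
  L <- ncol(mat)
  enc <- matrix(match(mat, aln$alphabet), nrow = n)
  sim <- matrix(0L, n, n)
  for (j in seq_len(L)) {
    sim <- sim + outer(enc[, j], enc[, j], "==")
  }
  cluster_size <- rowSums(sim / L >= 1 - theta)
  w <- 1 / cluster_size
  structure(list(weights = w, theta = theta, n_eff = sum(w)),
            class = "seq_weights")
}

#' Weighted single- and pair-site frequency tables
#'
#' Weighted empirical frequencies mixed with the uniform distribution:
#' `f = (1 - lambda) f_emp + lambda / q` for single sites and
#' `lambda / q^2` for pairs. These are the occurrence statistics a Potts
#' model is constrained to reproduce.
#'
#' @param aln An `"msa"` object.
#' @param w A `"seq_weights"` object (or NULL for uniform weights).
#' @param pseudocount_lambda Uniform-mixing fraction in `[0, 1)`
#'   (default 0).
#' @return A list of class `"freq_tables"` with `f_i` (L x q matrix),
#'   `f_ij` (L x L x q x q array; the diagonal holds `f_i` on its own
#'   diagonal), `pseudocount_lambda`, `alphabet`.
#' @export
compute_frequencies <- function(aln, w = NULL, pseudocount_lambda = 0) {
  stopifnot(inherits(aln, "msa"),
            pseudocount_lambda >= 0, pseudocount_lambda < 1)
  mat <- aln$matrix
  n <- nrow(mat)
  L <- ncol(mat)
  q <- length(aln$alphabet)
  weights <- if (is.null(w)) rep(1, n) else w$weights
  if (length(weights) != n) stop("weights do not match alignment rows")
  wn <- weights / sum(weights)
  enc <- matrix(match(mat, aln$alphabet), nrow = n)
  lam <- pseudocount_lambda

  # one-hot indicators per column, weighted
  onehot <- lapply(seq_len(L), function(j) {
    M <- matrix(0, n, q)
    M[cbind(seq_len(n), enc[, j])] <- 1
    M
  })
  f_i <- t(vapply(onehot, function(M) colSums(M * wn), numeric(q)))
  f_ij <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L)) {
    Wi <- onehot[[i]] * wn
    for (j in seq_len(L)) {
      if (j == i) {
        f_ij[i, i, , ] <- diag(f_i[i, ], nrow = q)
      } else {
        f_ij[i, j, , ] <- crossprod(Wi, onehot[[j]])
      }
    }
  }
  f_i <- (1 - lam) * f_i + lam / q
  f_ij <- (1 - lam) * f_ij + lam / q^2
  structure(list(f_i = f_i, f_ij = f_ij, pseudocount_lambda = lam,
                 alphabet = aln$alphabet),
            class = "freq_tables")
}
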
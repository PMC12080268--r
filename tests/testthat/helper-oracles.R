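# Independent brute-force oracles and small random generators used across
# the suite. These deliberately use naive loops, not the package's fast
# paths.

# gap plus the first q - 1 real amino-acid letters, so toy states are
# always valid substitution targets
toy_alphabet <- function(q) aa_alphabet()[seq_len(q)]

# random symmetric Potts model (gap-free focus sequence)
random_potts <- function(L, q, seed, h_sd = 0.7, j_sd = 0.3, with_J = TRUE) {
  set.seed(seed)
  alpha <- toy_alphabet(q)
  h <- matrix(rnorm(L * q, 0, h_sd), L, q)
  J <- array(0, dim = c(L, L, q, q))
  if (with_J) {
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        K <- matrix(rnorm(q * q, 0, j_sd), q, q)
        J[i, j, , ] <- K
        J[j, i, , ] <- t(K)
      }
    }
  }
  focus <- sample(alpha[-1], L, replace = TRUE)
  potts_model(h, J, alpha, focus_seq = focus)
}

# triple-loop statistical energy
brute_energy <- function(model, s) {
  if (is.character(s)) s <- match(s, model$alphabet)
  e <- 0
  for (i in seq_len(model$L)) e <- e + model$h[i, s[i]]
  for (i in seq_len(model$L)) {
    for (j in seq_len(model$L)) {
      if (i < j) e <- e + model$J[i, j, s[i], s[j]]
    }
  }
  e
}

# exhaustive Boltzmann distribution over all q^L sequences (state indices)
enumerate_boltzmann <- function(model) {
  L <- model$L; q <- model$q
  states <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
  en <- apply(states, 1, function(s) brute_energy(model, s))
  p <- exp(en - max(en))
  list(states = states, prob = p / sum(p))
}

# pairwise-identity weights by double loop
brute_weights <- function(mat, theta) {
  n <- nrow(mat)
  w <- numeric(n)
  for (s in seq_len(n)) {
    cnt <- 0
    for (t in seq_len(n)) {
      if (mean(mat[s, ] == mat[t, ]) >= 1 - theta) cnt <- cnt + 1
    }
    w[s] <- 1 / cnt
  }
  w
}

random_msa <- function(n, L, q, seed, gap_frac = 0.1) {
  set.seed(seed)
  # q = 21 means the real protein alphabet; smaller q a toy alphabet
  alpha <- if (q == 21) aa_alphabet() else toy_alphabet(q)
  mat <- matrix(sample(alpha[-1], n * L, replace = TRUE), n, L)
  gaps <- matrix(runif(n * L) < gap_frac, n, L)
  gaps[1, ] <- FALSE  # keep the focus row gap-free
  mat[gaps] <- "-"
  msa_from_matrix(mat, alphabet = alpha)
}

write_fasta_lines <- function(path, ids, seqs) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
}
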
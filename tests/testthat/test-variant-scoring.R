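# Variant parsing, delta E scoring, enumeration/ranking, epistasis
# decomposition and ddG run ingestion.

test_that("variant strings parse, canonicalize and validate", {
  v <- parse_variant("Q289G")
  expect_equal(v$pos, 289L)
  expect_equal(v$wt, "Q")
  expect_equal(v$mut, "G")
  # unsorted input canonicalizes by position
  d <- parse_variant("Q289G/S180T")
  expect_equal(d$name, "S180T/Q289G")
  expect_error(parse_variant("Q289Q"), "identical")
  expect_error(parse_variant("Q289G/Q289A"), "repeats")
  expect_error(parse_variant("Q289X"), "20 amino acids")
  expect_error(parse_variant("nonsense"), "cannot parse")
})

test_that("delta E matches its definition and closed forms", {
  m <- random_potts(6, 5, seed = 11)
  expect_equal(score_variant(m, NULL), 0)
  expect_equal(score_variant(m, ""), 0)

  # single substitution with J = 0: delta E = h_i(mut) - h_i(wt)
  m0 <- random_potts(4, 5, seed = 12, with_J = FALSE)
  wt <- m0$focus_seq
  alt <- setdiff(m0$alphabet[-1], wt[2])[1]
  v <- paste0(wt[2], 2, alt)
  expect_equal(score_variant(m0, v),
               m0$h[2, match(alt, m0$alphabet)] - m0$h[2, match(wt[2], m0$alphabet)])

  # unmodeled and mismatched positions error informatively
  expect_error(score_variant(m, "A99C"), "unmodeled position")
  wrong_wt <- setdiff(m$alphabet[-1], m$focus_seq[1])[1]
  some_mut <- setdiff(m$alphabet[-1], c(wrong_wt, m$focus_seq[1]))[1]
  expect_error(score_variant(m, paste0(wrong_wt, 1, some_mut)), "wild-type mismatch")
})

test_that("incremental double-variant delta E equals the full energy difference", {
  for (trial in 1:100) {
    m <- random_potts(5, 5, seed = trial)
    wt <- m$focus_seq
    set.seed(1000 + trial)
    ij <- sort(sample(1:5, 2))
    aa <- m$alphabet[-1]
    mut1 <- sample(setdiff(aa, wt[ij[1]]), 1)
    mut2 <- sample(setdiff(aa, wt[ij[2]]), 1)
    v <- paste0(wt[ij[1]], ij[1], mut1, "/", wt[ij[2]], ij[2], mut2)
    mutant <- wt
    mutant[ij] <- c(mut1, mut2)
    expect_equal(score_variant(m, v),
                 brute_energy(m, mutant) - brute_energy(m, wt),
                 tolerance = 1e-12)
  }
})

test_that("delta E is gauge-invariant and antisymmetric", {
  m <- random_potts(5, 6, seed = 23)
  z <- to_zero_sum_gauge(m)
  wt <- m$focus_seq
  aa <- m$alphabet[-1]
  set.seed(24)
  for (k in 1:20) {
    i <- sample(1:5, 1)
    mut <- sample(setdiff(aa, wt[i]), 1)
    v <- paste0(wt[i], i, mut)
    de <- score_variant(m, v)
    expect_equal(score_variant(z, v), de, tolerance = 1e-8)
    # swap roles: make the mutant the focus sequence
    m_swapped <- m
    m_swapped$focus_seq[i] <- mut
    expect_equal(score_variant(m_swapped, paste0(mut, i, wt[i])), -de,
                 tolerance = 1e-12)
  }
})

test_that("ranking matches exhaustive brute force on a toy model", {
  m <- random_potts(3, 4, seed = 33)
  wt <- m$focus_seq
  aa <- m$alphabet[-1]

  brute_singles <- do.call(rbind, lapply(1:3, function(i) {
    do.call(rbind, lapply(setdiff(aa, wt[i]), function(a) {
      mutant <- wt; mutant[i] <- a
      data.frame(variant = paste0(wt[i], i, a),
                 delta_e = brute_energy(m, mutant) - brute_energy(m, wt))
    }))
  }))
  brute_singles <- brute_singles[order(-brute_singles$delta_e, brute_singles$variant), ]
  got <- enumerate_and_rank(m, "single", nrow(brute_singles))
  expect_equal(got$variant, brute_singles$variant)
  expect_equal(got$delta_e, brute_singles$delta_e, tolerance = 1e-12)
  expect_equal(got$rank, seq_len(nrow(got)))

  pairs <- combn(3, 2)
  brute_doubles <- do.call(rbind, apply(pairs, 2, function(ij) {
    do.call(rbind, lapply(setdiff(aa, wt[ij[1]]), function(a) {
      do.call(rbind, lapply(setdiff(aa, wt[ij[2]]), function(b) {
        mutant <- wt; mutant[ij] <- c(a, b)
        data.frame(variant = paste0(wt[ij[1]], ij[1], a, "/", wt[ij[2]], ij[2], b),
                   delta_e = brute_energy(m, mutant) - brute_energy(m, wt))
      }))
    }))
  }))
  top <- enumerate_and_rank(m, "double", 10)
  brute_sorted <- brute_doubles[order(-brute_doubles$delta_e), ]
  expect_equal(top$delta_e, brute_sorted$delta_e[1:10], tolerance = 1e-12)
  expect_equal(top$variant, brute_sorted$variant[1:10])

  expect_warning(all_d <- enumerate_and_rank(m, "double", 10000), "exceeds")
  expect_equal(nrow(all_d), nrow(brute_doubles))
})

test_that("the fixture model reproduces the printed single and double rankings", {
  m <- build_fixture_model()
  t1 <- load_fixture("T1")
  singles <- enumerate_and_rank(m, "single", 20)
  expect_equal(singles$variant[1], "Q289G")
  expect_equal(singles$delta_e[1], 3.13)
  expect_equal(setNames(singles$delta_e, singles$variant)[t1$ev_variant],
               setNames(t1$ev_delta_e, t1$ev_variant))

  doubles <- enumerate_and_rank(m, "double", 20)
  expect_equal(doubles$variant[1], "V226I/Q289G")
  expect_equal(doubles$delta_e[1], 5.83)
})

test_that("epistasis decomposition is exact and matches the coupling term", {
  m0 <- random_potts(4, 5, seed = 41, with_J = FALSE)
  wt <- m0$focus_seq
  aa <- m0$alphabet[-1]
  v <- paste0(wt[1], 1, setdiff(aa, wt[1])[1], "/",
              wt[3], 3, setdiff(aa, wt[3])[1])
  expect_equal(epistasis_decompose(m0, v)$coupling_gap, 0)

  m <- random_potts(4, 5, seed = 42)
  m$focus_seq <- wt  # same wild type as the field-only model
  rec <- epistasis_decompose(m, v)
  expect_equal(rec$coupling_gap,
               rec$delta_e_double - rec$delta_e_a - rec$delta_e_b,
               tolerance = 1e-12)
  # four-term coupling difference at the substituted pair
  vv <- parse_variant(v)
  a_wt <- match(wt[1], m$alphabet); a_mut <- match(vv$mut[1], m$alphabet)
  b_wt <- match(wt[3], m$alphabet); b_mut <- match(vv$mut[2], m$alphabet)
  expect_equal(rec$coupling_gap,
               m$J[1, 3, a_mut, b_mut] - m$J[1, 3, a_mut, b_wt] -
                 m$J[1, 3, a_wt, b_mut] + m$J[1, 3, a_wt, b_wt],
               tolerance = 1e-9)
  # and the additivity identity holds exactly for the fast scorer
  expect_equal(score_variant(m, v),
               rec$delta_e_a + rec$delta_e_b + rec$coupling_gap,
               tolerance = 1e-9)
})

test_that("fixture epistasis gaps reproduce the printed table arithmetic", {
  m <- build_fixture_model()
  expect_equal(epistasis_decompose(m, "S180T/Q289G")$coupling_gap,
               4.43 - (1.26 + 3.13))
  expect_equal(epistasis_decompose(m, "P111I/Q289G")$coupling_gap,
               5.47 - (2.42 + 3.13))
  # score-table route gives the same numbers
  scores <- rbind(enumerate_and_rank(m, "single", 20)[, c("variant", "delta_e")],
                  enumerate_and_rank(m, "double", 20)[, c("variant", "delta_e")])
  rec <- epistasis_decompose(double = "S180T/Q289G", score_table = scores)
  expect_equal(rec$coupling_gap, 4.43 - (1.26 + 3.13))
  expect_error(epistasis_decompose(double = "A1C/D2E", score_table = scores),
               "missing constituent")
})

test_that("ddG run aggregation ranks stabilizing variants first", {
  runs <- data.frame(variant = "X1Y", run = 1:5, ddg = rep(-5.35, 5))
  agg <- ingest_ddg_runs(runs)
  expect_equal(agg$ddg_mean, -5.35)
  expect_equal(agg$ddg_sem, 0)

  fix <- ingest_ddg_runs(fixture_ddg_runs())
  expect_equal(fix$variant[1], "D138N")
  expect_equal(fix$ddg_mean[1], -5.35)
  expect_equal(fix$ddg_sem[1], 0.02, tolerance = 1e-12)
  t1 <- load_fixture("T1")
  expect_equal(fix$variant, t1$foldx_variant)
  expect_equal(fix$ddg_mean, t1$foldx_ddg, tolerance = 1e-12)
  expect_equal(fix$ddg_sem, t1$foldx_ddg_sem, tolerance = 1e-12)

  # zero-mean runs are excluded by the stabilizing filter
  zero <- data.frame(variant = "A1C", run = 1:3, ddg = c(-1, 0, 1))
  both <- rbind(zero, data.frame(variant = "A1D", run = 1:3, ddg = c(-2, -1, -3)))
  kept <- ingest_ddg_runs(both, stabilizing_only = TRUE)
  expect_equal(kept$variant, "A1D")

  expect_error(ingest_ddg_runs(rbind(zero, zero)), "duplicate")
  bad <- zero; bad$ddg <- as.character(bad$ddg)
  expect_error(ingest_ddg_runs(bad), "non-numeric")
})

test_that("ranking is stable under input permutation of the model", {
  # permuting positions permutes names but not the ranked order of delta E
  m <- random_potts(4, 5, seed = 55)
  r1 <- enumerate_and_rank(m, "single", 10)
  r2 <- enumerate_and_rank(m, "single", 10)
  expect_identical(r1, r2)
})
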
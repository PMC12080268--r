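# Activity normalization, classification, hit rates, melting and decay
# fits, delta Tm arithmetic, correlation and experimental epistasis.

test_that("activity normalization is exact on clean plates and flags inactives", {
  p <- make_plate(c(V1 = 1, V2 = 1), wt_signal = 1, background = 0.1,
                  n_replicates = 3, noise_frac = 0, seed = 1)
  res <- normalize_activity(p)
  expect_equal(res$fold_vs_wt, rep(1, 3))
  expect_false(any(res$inactive))

  p0 <- make_plate(c(dead = 0), wt_signal = 1, background = 0.1,
                   n_replicates = 3, noise_frac = 0, seed = 1)
  res0 <- normalize_activity(p0)
  dead <- res0[res0$variant == "dead", ]
  expect_equal(dead$fold_vs_wt, 0)
  expect_true(dead$inactive)

  expect_error(normalize_activity(p[p$variant != "WT", ]), "missing")
})

test_that("activity normalization is scale-invariant", {
  p <- make_plate(c(V1 = 2.5, V2 = 0.4), wt_signal = 1.2, background = 0.15,
                  n_replicates = 4, noise_frac = 0.05, seed = 7)
  res <- normalize_activity(p)
  p_scaled <- p
  p_scaled$signal <- p$signal * 37.5
  res_scaled <- normalize_activity(p_scaled)
  expect_equal(res_scaled$fold_vs_wt, res$fold_vs_wt, tolerance = 1e-12)
  expect_equal(res_scaled$sem, res$sem, tolerance = 1e-12)
})

test_that("a 3.6-fold activity is recovered from a noisy replicated plate", {
  p <- make_plate(c(best = 3.6), wt_signal = 1.0, background = 0.1,
                  n_replicates = 3, noise_frac = 0.05, seed = 4)
  res <- normalize_activity(p, propagate_wt = TRUE)
  best <- res[res$variant == "best", ]
  expect_lt(abs(best$fold_vs_wt - 3.6), 2 * best$sem)
})

test_that("classification against the wild type follows the z rule", {
  expect_equal(classify_vs_wt(5, 0.1, 5, 0.1), "similar")
  expect_equal(classify_vs_wt(5, 0, 5, 0), "similar")
  expect_equal(classify_vs_wt(6, 0, 5, 0), "improved")
  # value 10 combined-SEMs above the wild type
  comb <- sqrt(0.1^2 + 0.1^2)
  expect_equal(classify_vs_wt(5 + 10 * comb, 0.1, 5, 0.1), "improved")
  expect_equal(classify_vs_wt(5 - 10 * comb, 0.1, 5, 0.1), "reduced")
  # antisymmetry: swapping variant and wild type flips the label
  set.seed(3)
  for (k in 1:20) {
    v <- runif(1, 0, 10); wv <- runif(1, 0, 10)
    s <- runif(1, 0.01, 1); ws <- runif(1, 0.01, 1)
    lab <- classify_vs_wt(v, s, wv, ws)
    swapped <- classify_vs_wt(wv, ws, v, s)
    expect_equal(swapped, switch(lab, improved = "reduced",
                                 reduced = "improved", similar = "similar"))
  }
})

test_that("the structure-arm fixture has 16 of 20 variants below the wild-type Tm", {
  t2 <- load_fixture("T2")
  fx <- t2[t2$method == "FoldX" & t2$variant != "WT", ]
  wt_tm <- t2$tm[t2$method == "FoldX" & t2$variant == "WT"]
  expect_equal(nrow(fx), 20L)
  expect_equal(sum(fx$tm < wt_tm), 16L)
})

test_that("hit rates are simple percentages with guarded inputs", {
  expect_equal(hit_rate(10, 20), 50)
  expect_equal(hit_rate(16, 20), 80)
  expect_equal(hit_rate(0, 7), 0)
  expect_error(hit_rate(1, 0))
  expect_error(hit_rate(5, 3))
})

test_that("melting fits recover Tm and flag transition-free signals", {
  clean <- make_melting_curve(82.2, noise_sd = 0,
                              baselines = list(pre = 0.85, post = 1.05,
                                               pre_slope = 0, post_slope = 0))
  fd <- fit_melting(clean, "derivative")
  fs <- fit_melting(clean, "sigmoid")
  expect_lt(abs(fd$tm - 82.2), 0.1)
  expect_lt(abs(fs$tm - 82.2), 0.1)
  expect_lt(abs(fd$tm - fs$tm), 0.5)

  # the generated curve's midpoint lies halfway between the baselines
  at_tm <- clean$signal[clean$temperature == 82]
  expect_lt(abs(at_tm - (0.85 + 1.05) / 2), 0.02)

  lin <- data.frame(temperature = seq(20, 95, 1),
                    signal = 0.01 * seq(20, 95, 1))
  flagged <- fit_melting(lin, "derivative")
  expect_false(flagged$transition)
  expect_true(is.na(flagged$tm))
})

test_that("derivative Tm errors stay within 0.3 degC on noisy curves", {
  amp <- 0.2
  errs <- vapply(1:100, function(s) {
    cv <- make_melting_curve(85, noise_sd = 0.01 * amp, seed = s)
    abs(fit_melting(cv, "derivative")$tm - 85)
  }, numeric(1))
  expect_gte(sum(errs <= 0.3), 95)
})

test_that("melting and decay estimators are consistent as noise shrinks", {
  amp <- 0.2
  bias_at <- function(noise) {
    mean(vapply(1:20, function(s) {
      fit_melting(make_melting_curve(80, noise_sd = noise * amp, seed = s))$tm - 80
    }, numeric(1)))
  }
  biases <- abs(vapply(c(0.05, 0.01, 0.001), bias_at, numeric(1)))
  expect_lt(biases[3], 0.05)
  expect_lte(biases[3], biases[1] + 0.02)

  dbias_at <- function(noise) {
    mean(vapply(1:20, function(s) {
      fit_decay(make_decay_series(40, noise_frac = noise, seed = s))$half_life - 40
    }, numeric(1)))
  }
  dbiases <- abs(vapply(c(0.1, 0.02, 0.002), dbias_at, numeric(1)))
  expect_lt(dbiases[3], 0.1)
  expect_lte(dbiases[3], dbiases[1] + 0.05)
})

test_that("first-order decay fitting recovers half-lives", {
  clean <- make_decay_series(40, noise_frac = 0)
  f <- fit_decay(clean)
  expect_equal(f$half_life, 40, tolerance = 1e-6)

  flat <- data.frame(time = seq(0, 150, 15), activity = 100)
  nf <- fit_decay(flat)
  expect_false(nf$decay)
  expect_true(is.na(nf$half_life))

  noisy <- make_decay_series(104, noise_frac = 0.05, seed = 2)
  fn <- fit_decay(noisy)
  expect_lt(abs(fn$half_life - 104), 2 * fn$half_life_se)

  expect_error(fit_decay(data.frame(time = c(10, 20, 30), activity = 1:3)), "t = 0")
})

test_that("delta Tm arithmetic reproduces the printed differences", {
  expect_equal(delta_tm(85.0, 0.2, 82.2, 0.1)[["delta_tm"]], 2.8)
  expect_equal(delta_tm(85.9, 0.1, 82.2, 0.1)[["delta_tm"]], 3.7)
  expect_equal(delta_tm(82.2, 0.1, 82.2, 0.1)[["delta_tm"]], 0)
  expect_error(delta_tm(NA, 0.1, 82.2, 0.1), "missing")
})

test_that("printed single- and double-variant delta Tm values follow from the tables", {
  t2 <- load_fixture("T2")
  t3 <- load_fixture("T3")
  wt <- list(tm = 82.2, sem = 0.1)
  dtm2 <- function(v, method) {
    r <- t2[t2$variant == v & t2$method == method, ]
    delta_tm(r$tm, r$tm_sem, wt$tm, wt$sem)[["delta_tm"]]
  }
  expect_equal(dtm2("Q289G", "EVmutation"), 2.8)
  expect_equal(dtm2("S280L", "FoldX"), 2.0)
  expect_equal(dtm2("S280M", "FoldX"), 1.9)
  expect_equal(dtm2("E175M", "FoldX"), -26.9)
  dtm3 <- function(v) {
    r <- t3[t3$variant == v, ]
    delta_tm(r$tm, r$tm_sem, wt$tm, wt$sem)[["delta_tm"]]
  }
  expect_equal(dtm3("S180T/Q289G"), 3.7)
  expect_equal(dtm3("P111I/Q289G"), 3.5)
  expect_equal(dtm3("P111V/Q289G"), 3.4)
  expect_equal(dtm3("V226I/Q289G"), 3.2)
  expect_equal(dtm3("T236Q/Q289G"), 3.1)
})

test_that("Spearman correlation matches a rank-then-Pearson oracle", {
  expect_equal(correlate_spearman(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(correlate_spearman(1:5, c(10, 8, 6, 4, 2))$rho, -1)

  set.seed(6)
  x <- rnorm(15); y <- 0.5 * x + rnorm(15)
  got <- correlate_spearman(x, y)
  oracle <- stats::cor(rank(x), rank(y))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  # t-approximation p-value on n - 2 df
  tstat <- oracle * sqrt(13 / (1 - oracle^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), 13), tolerance = 1e-10)

  const <- correlate_spearman(rep(1, 5), 1:5)
  expect_true(const$flagged)
  expect_true(is.na(const$rho))
})

test_that("experimental epistasis deviations carry the right sign", {
  add <- experimental_epistasis(7, 5, 4, wt = 2, mode = "additive")
  expect_equal(add$deviation, 0)
  expect_equal(add$sign, "additive")

  mult <- experimental_epistasis(3, 2, 2, mode = "multiplicative")
  expect_equal(mult$deviation, -1)
  expect_equal(mult$sign, "negative")

  # synthetic fold-change panel with injected epistasis, 5% assay noise
  set.seed(9)
  hits <- 0
  n_panel <- 100
  for (k in seq_len(n_panel)) {
    fa <- runif(1, 1.2, 2.5); fb <- runif(1, 1.2, 2.5)
    eps <- sample(c(-1, 1), 1) * runif(1, 0.5, 1.5)
    noisy <- function(x) x * (1 + rnorm(1, 0, 0.05))
    dev <- experimental_epistasis(noisy(fa * fb + eps), noisy(fa), noisy(fb),
                                  mode = "multiplicative")
    if ((dev$deviation > 0) == (eps > 0)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("stability reports combine metrics, classes and hit rates", {
  t3 <- load_fixture("T3")
  recs <- data.frame(variant = t3$variant, tm = t3$tm, tm_sem = t3$tm_sem)
  rep <- stability_report(recs, wt_name = "WT")
  expect_equal(rep$table$delta_tm[rep$table$variant == "S180T/Q289G"], 3.7)
  expect_true(rep$summary$tm_hit_rate >= 0 && rep$summary$tm_hit_rate <= 100)
  tabf <- withr::local_tempfile(fileext = ".tsv")
  sumf <- withr::local_tempfile(fileext = ".json")
  write_stability_report(rep, tabf, sumf)
  expect_true(file.exists(tabf) && file.exists(sumf))
  expect_equal(jsonlite::fromJSON(sumf)$n_variants, 21L)
})
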
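test_that("delta1 threshold is the scaled normal quantile", {
  # alpha = 1 disables the threshold for any sigma0
  expect_equal(delta1_threshold(1, c(0.1, 0.5, 2)), c(0, 0, 0))
  expect_equal(delta1_threshold(0.05, 0.5), 0.5 * qnorm(0.975))
  expect_equal(delta1_threshold(0.05, 0.5), 0.97998, tolerance = 1e-5)
  # strictly decreasing in alpha
  al <- c(0.01, 0.05, 0.2, 0.5, 1)
  expect_true(all(diff(delta1_threshold(al, 0.5)) < 1e-12))
  expect_error(delta1_threshold(0, 0.5), "infinite")
})

test_that("delta2 threshold is the scaled t quantile", {
  expect_equal(delta2_threshold(0.5, c(0.2, 1), c(5, 30)), c(0, 0))
  expect_equal(delta2_threshold(0.2, 0.3, 8), 0.3 * qt(0.8, 8))
  expect_equal(delta2_threshold(0.2, 0.6, 8), 2 * delta2_threshold(0.2, 0.3, 8))
  expect_error(delta2_threshold(0.7, 0.3, 8), "beta_th")
})

test_that("conditional Type II error matches the t alternative", {
  # just past the significance threshold: beta -> 0.5
  expect_equal(conditional_type2_error(0.5 + 1e-12, 0.5, 0.2, 10), 0.5,
               tolerance = 1e-9)
  # effect 10 s beyond the threshold: essentially full power
  expect_lt(conditional_type2_error(0.5 + 10 * 0.2, 0.5, 0.2, 20), 1e-8)
  # inverse identity: at |d| - delta1 = s T^-1(0.8, df), beta = 0.2 exactly
  for (df in c(4, 9, 18)) {
    d <- 0.3 + 0.25 * qt(0.8, df)
    expect_equal(conditional_type2_error(d, 0.3, 0.25, df), 0.2)
  }
  expect_error(conditional_type2_error(0.2, 0.5, 0.2, 10), "only for")
})

test_that("p threshold reduces to 2 beta_th at alpha = 1", {
  for (beta in c(0.05, 0.2, 0.5))
    for (df in c(3, 10, 40))
      expect_equal(p_threshold(1, beta, 0.3, 0.2, df), 2 * beta,
                   tolerance = 1e-12)
  expect_equal(p_threshold(0.05, 0.2, 1, 1, 18),
               2 * (1 - pt(qnorm(0.975) + qt(0.8, 18), 18)))
  # decreasing in sigma0/s
  ps <- p_threshold(0.05, 0.2, c(0.5, 1, 2), 1, 18)
  expect_true(all(diff(ps) < 0))
})

test_that("selection is near-empty on pure-null data at default settings", {
  sim <- generate_dataset(null_config(seed = 301))
  sm <- summarize_features(sim$dataset)
  m <- estimate_null_model(sm)
  res <- select_and_rank(sm, m)        # alpha 0.05, beta 0.2, filter on
  expect_lt(mean(res$passes_selection), 0.02)
})

test_that("a strong planted effect is ranked first", {
  set.seed(302)
  n1 <- n2 <- 10
  np <- 1000
  v <- 0.25
  m0 <- matrix(rnorm(np * (n1 + n2), mean = 8, sd = sqrt(v)), nrow = np)
  s0 <- sqrt(v / n1 + v / n2)
  m0[1, 1:n1] <- rnorm(n1, 8 + 4 * s0 / 2, sd = 0.1)   # low variance, big d
  m0[1, (n1 + 1):(n1 + n2)] <- rnorm(n2, 8 - 4 * s0 / 2, sd = 0.1)
  ds <- expression_dataset(m0, rep(1:2, c(n1, n2)))
  sm <- summarize_features(ds)
  res <- select_and_rank(sm, estimate_null_model(sm))
  expect_equal(res$rank[1], 1L)
})

test_that("threshold form and power form select identical sets", {
  for (seed in 303:306) {
    cfg <- simulation_config(seed = seed, n_features = 2000L, pi = 0.05,
                             profile = variance_profile("mas5"))
    sim <- generate_dataset(cfg)
    sm <- summarize_features(sim$dataset)
    m <- estimate_null_model(sm)
    for (vf in c(TRUE, FALSE)) {
      p <- dfc_parameters(alpha = 0.05, beta_th = 0.2, variance_filter = vf)
      res <- select_and_rank(sm, m, p)
      expect_identical(res$passes_selection, passes_by_power(res, p))
    }
  }
})

test_that("selected features respect the implied t-test p bound", {
  cfg <- simulation_config(seed = 307, n_features = 3000L, pi = 0.05)
  sim <- generate_dataset(cfg)
  sm <- summarize_features(sim$dataset)
  m <- estimate_null_model(sm)
  res <- select_and_rank(sm, m)
  sel <- res$passes_selection
  expect_gt(sum(sel), 0)
  expect_true(all(res$t_p_stab[sel] <= res$p_th[sel]))
})

test_that("alpha=1, beta=0.5, filter off reduces to pure ranking", {
  cfg <- simulation_config(seed = 308, n_features = 2000L, pi = 0.05)
  sim <- generate_dataset(cfg)
  sm <- summarize_features(sim$dataset)
  m <- estimate_null_model(sm)
  res <- select_and_rank(sm, m,
                         dfc_parameters(1, 0.5, variance_filter = FALSE))
  expect_true(all(res$passes_selection[abs(res$d) > 0]))
  # rank is exactly the |Z_d| order, stable in input order
  expect_equal(order(res$rank), order(-abs(res$z_score)))
  # p-values are the two-sided normal tail of the score
  expect_equal(res$p_value, 2 * pnorm(-abs(res$z_score)))
})

test_that("DFC reduces exactly to the Welch t selection", {
  cfg <- simulation_config(seed = 309, n_features = 2000L, pi = 0.05)
  sim <- generate_dataset(cfg)
  sm <- summarize_features(sim$dataset)
  m <- estimate_null_model(sm)
  res <- select_and_rank(sm, m, dfc_parameters(1, 0.2, variance_filter = FALSE),
                         use_v_bar_ee = FALSE, use_v0 = FALSE)
  wt <- welch_t_test(sim$dataset)
  # identical ranking
  expect_equal(order(-abs(res$z_score)), order(-abs(wt$t)))
  # selection set equals {welch p <= 2 beta_th} (continuous data: no boundary ties)
  expect_identical(res$passes_selection, wt$p <= 0.4)
})

test_that("a global intensity scaling leaves the ranking unchanged", {
  cfg <- simulation_config(seed = 310, n_features = 2000L, pi = 0.05)
  sim <- generate_dataset(cfg)
  sm1 <- summarize_features(sim$dataset)
  ds2 <- expression_dataset(sim$dataset$values + log2(3),  # 3x intensities
                            sim$dataset$class_labels)
  sm2 <- summarize_features(ds2)
  r1 <- select_and_rank(sm1, estimate_null_model(sm1))
  r2 <- select_and_rank(sm2, estimate_null_model(sm2))
  expect_equal(r1$rank, r2$rank)
})

test_that("parameter validation", {
  expect_error(dfc_parameters(alpha = 0), "alpha")
  expect_error(dfc_parameters(beta_th = 0.6), "beta_th")
})
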
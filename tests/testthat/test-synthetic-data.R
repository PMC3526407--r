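test_that("variance profiles are positive and shaped as documented", {
  flat <- variance_profile("flat", v = 0.4)
  expect_equal(variance_profile_value(flat, c(0, 8, 16)), rep(0.4, 3))

  # exponential halving per 1/b log2 units when the floor is 0
  mas5 <- variance_profile("mas5", a = 4, b = 0.5, c = 0)
  mu <- c(2, 5, 9)
  expect_equal(variance_profile_value(mas5, mu + 1 / 0.5) /
                 variance_profile_value(mas5, mu), rep(0.5, 3))

  rma <- variance_profile("rma")
  grid <- seq(0, 16, by = 0.25)
  for (p in list(flat, mas5 <- variance_profile("mas5"), rma))
    expect_true(all(variance_profile_value(p, grid) > 0))
  # rma: rise at low expression, plateau at high
  v_rma <- variance_profile_value(rma, grid)
  expect_true(all(diff(v_rma) <= 0))
  expect_lt(v_rma[length(v_rma)] / v_rma[1], 0.1)

  expect_error(variance_profile("mas5", a = -1), "parameters")
  expect_error(variance_profile("flat", v = 0), "v > 0")
})

test_that("generation is deterministic and leaves the RNG alone", {
  cfg <- simulation_config(n_features = 500L, seed = 9L)
  a <- generate_dataset(cfg)
  set.seed(77)
  before <- .Random.seed
  b <- generate_dataset(cfg)
  expect_identical(before, .Random.seed)     # caller RNG untouched
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth, b$truth)
})

test_that("the DE prior is honoured exactly and symmetric in sign", {
  cfg <- simulation_config(n_features = 4000L, pi = 0.05, seed = 10L)
  sim <- generate_dataset(cfg)
  expect_equal(sum(sim$truth$is_de), 200L)
  expect_true(all(sim$truth$d_true[!sim$truth$is_de] == 0))
  signs <- sign(sim$truth$d_true[sim$truth$is_de])
  expect_gt(mean(signs == 1), 0.35)          # roughly balanced
  expect_gt(mean(signs == -1), 0.35)
  expect_true(all(abs(sim$truth$d_true[sim$truth$is_de]) >= 0.5))
})

test_that("pure-null data yields uniform Welch t p-values", {
  sim <- generate_dataset(null_config(seed = 11L))
  wt <- welch_t_test(sim$dataset)
  ks <- suppressWarnings(ks.test(wt$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("FFPE compression halves the realized effect sizes", {
  ratios <- vapply(1:10, function(seed) {
    full <- generate_dataset(simulation_config(n_features = 2000L, pi = 0.05,
                                               ffpe_compression = 1, seed = seed))
    comp <- generate_dataset(simulation_config(n_features = 2000L, pi = 0.05,
                                               ffpe_compression = 0.5, seed = seed))
    sm_f <- summarize_features(full$dataset)
    sm_c <- summarize_features(comp$dataset)
    mean(abs(sm_c$d[comp$truth$is_de])) / mean(abs(sm_f$d[full$truth$is_de]))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
})

test_that("mu_shift lowers expression without touching effects", {
  a <- generate_dataset(simulation_config(n_features = 1000L, seed = 12L))
  b <- generate_dataset(simulation_config(n_features = 1000L, seed = 12L,
                                          mu_shift = 3))
  expect_equal(b$truth$mu_true, a$truth$mu_true - 3)
  expect_equal(b$truth$d_true, a$truth$d_true)
})

test_that("invalid configurations are rejected with field names", {
  expect_error(simulation_config(pi = 0.5), "pi")
  expect_error(simulation_config(n1 = 1), "n1")
  expect_error(simulation_config(ffpe_compression = 0), "ffpe_compression")
  expect_error(simulation_config(ffpe_compression = 1.2), "ffpe_compression")
  expect_error(simulation_config(mu_range = c(5, 4)), "mu_range")
  expect_error(simulation_config(effect = list(d_min = -1, shape = 1, scale = 1)),
               "effect")
})

test_that("Type I behaviour on pure-null data: delta1 calibrated, Z_d conservative", {
  sim <- generate_dataset(null_config(seed = 13L))
  sm <- summarize_features(sim$dataset)
  m <- estimate_null_model(sm)
  res <- select_and_rank(sm, m, dfc_parameters(1, 0.5, variance_filter = FALSE))

  # the alpha threshold itself is calibrated: P(|d| > delta1(0.05)) ~ 0.05
  ev <- evaluate_null_model(m, sm$mu)
  rej_d1 <- mean(abs(sm$d) > delta1_threshold(0.05, ev$sigma0))
  expect_gte(rej_d1, 0.03)
  expect_lte(rej_d1, 0.08)

  # the score's normal p is conservative by construction: on ideal null data
  # sigma0^2 ~ vsd, so the denominator counts the sampling noise twice and
  # Z_d ~ N(0, 1/2); the rejection rate sits near 2(1 - Phi(1.96 sqrt(2)))
  rej_z <- mean(res$p_value < 0.05)
  expect_lt(rej_z, 0.05)
  expect_lt(abs(rej_z - 2 * pnorm(-qnorm(0.975) * sqrt(2))), 0.01)
})

test_that("DFC ranking beats |d| under strong expression-dependent variance", {
  # DE effects in local signal-to-noise units (1.5 sigma0 upward): |d| has
  # no handle on the variance trend, the normalized score does
  gains <- vapply(1:10, function(seed) {
    cfg <- simulation_config(n_features = 5000L, pi = 0.02, seed = 600 + seed,
                             profile = variance_profile("mas5"),
                             effect = list(d_min = 1.5, shape = 1.5,
                                           scale = 0.6, relative = TRUE))
    sim <- generate_dataset(cfg)
    sm <- summarize_features(sim$dataset)
    res <- select_and_rank(sm, estimate_null_model(sm),
                           dfc_parameters(1, 0.5, variance_filter = FALSE))
    auc(roc_curve(abs(res$z_score), sim$truth$is_de)) -
      auc(roc_curve(fold_change_ranker(sm), sim$truth$is_de))
  }, numeric(1))
  expect_gt(mean(gains), 0)
})
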
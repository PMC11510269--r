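test_that("Wald ratio and its delta-method SE follow hand arithmetic", {
  w <- mr_wald_ratio(gamma = 0.1, se_gamma = 0.02, Gamma = 0.02,
                     se_Gamma = 0.01)
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.1)
  expect_equal(mr_wald_ratio(0.1, 0.02, 0, 0.01)$beta, 0)
  # second-order term adds Gamma^2 se_gamma^2 / gamma^4 to the variance
  w2 <- mr_wald_ratio(0.1, 0.02, 0.02, 0.01, second_order = TRUE)
  expect_equal(w2$se, sqrt(0.1^2 + 0.02^2 * 0.02^2 / 0.1^4))
  expect_error(mr_wald_ratio(0, 0.02, 0.1, 0.01, rsid = "rs9"),
               class = "mr_division_error")
})

test_that("IVW closed form matches hand evaluation and Wald consistency", {
  h <- make_hset(gamma = c(0.1, 0.2, 0.1), Gamma = c(0.02, 0.04, 0.02),
                 se_Gamma = c(0.01, 0.01, 0.01))
  est <- mr_ivw(h, mode = "fixed")
  expect_equal(est$beta, 0.2, tolerance = 1e-14)
  expect_equal(est$heterogeneity_q, 0, tolerance = 1e-20)
  # identical Wald ratios -> IVW equals that ratio; Q = 0 -> modes agree
  expect_equal(mr_ivw(h)$se, est$se)
  expect_equal(est$ci_low, est$beta - qnorm(0.975) * est$se, tolerance = 1e-10)
  h1 <- make_hset(0.1, 0.02, 0.01)
  expect_error(mr_ivw(h1), class = "mr_insufficient_instruments_error")
})

test_that("IVW agrees with a generic weighted-regression solver to 1e-10", {
  for (seed in 1:100) {
    inst <- random_instance(k = sample(5:40, 1), seed = seed)
    h <- make_hset(inst$gamma, inst$Gamma, inst$se_Gamma)
    fit <- lm(inst$Gamma ~ 0 + inst$gamma, weights = 1 / inst$se_Gamma^2)
    expect_equal(mr_ivw(h, mode = "fixed")$beta,
                 unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("multiplicative random effects inflate the IVW SE only when Q exceeds its df", {
  set.seed(21)
  k <- 20
  gamma <- runif(k, 0.05, 0.2)
  # heterogeneous outcome effects -> Q > k - 1
  h <- make_hset(gamma, 0.3 * gamma + rnorm(k, 0, 0.05), rep(0.01, k))
  fe <- mr_ivw(h, mode = "fixed")
  mre <- mr_ivw(h)
  expect_gt(mre$heterogeneity_q, k - 1)
  expect_equal(mre$se, fe$se * sqrt(mre$heterogeneity_q / (k - 1)))
})

test_that("Egger slope and intercept match the weighted-regression oracle", {
  for (seed in 1:20) {
    inst <- random_instance(k = 30, seed = seed)
    # orient gamma >= 0 as the estimator does, then compare against lm
    flip <- sign(inst$gamma)
    x <- inst$gamma * flip
    y <- inst$Gamma * flip
    fit <- lm(y ~ x, weights = 1 / inst$se_Gamma^2)
    eg <- mr_egger(make_hset(inst$gamma, inst$Gamma, inst$se_Gamma))
    expect_equal(eg$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("adding a constant pleiotropic offset shifts the Egger intercept, not the slope", {
  inst <- random_instance(k = 25, seed = 3)
  inst$gamma <- abs(inst$gamma)          # already oriented
  se_eq <- rep(0.02, 25)                 # equal weights
  e0 <- mr_egger(make_hset(inst$gamma, inst$Gamma, se_eq))
  e1 <- mr_egger(make_hset(inst$gamma, inst$Gamma + 0.05, se_eq))
  expect_equal(e1$intercept, e0$intercept + 0.05, tolerance = 1e-12)
  expect_equal(e1$slope$beta, e0$slope$beta, tolerance = 1e-12)
  expect_error(mr_egger(make_hset(c(0.1, 0.2), c(0.02, 0.04), c(0.01, 0.01))),
               class = "mr_insufficient_instruments_error")
})

test_that("weighted median reduces to the ordinary median under equal weights", {
  h <- make_hset(gamma = c(1, 1, 1), Gamma = c(0.1, 0.2, 0.9),
                 se_Gamma = c(1, 1, 1))
  est <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.2)
  set.seed(9)
  for (k in c(5, 8, 11)) {
    ratios <- rnorm(k)
    h2 <- make_hset(rep(1, k), ratios, rep(1, k))
    expect_equal(mr_weighted_median(h2, n_boot = 100, seed = 2)$beta,
                 median(ratios))
  }
})

test_that("weighted median is permutation-invariant and robust to one outlier", {
  inst <- random_instance(k = 11, seed = 6)
  inst$Gamma[1] <- inst$Gamma[1] + 0.5   # one wildly pleiotropic SNP
  h <- make_hset(inst$gamma, inst$Gamma, inst$se_Gamma)
  est <- mr_weighted_median(h, n_boot = 500, seed = 4)
  perm <- sample(11)
  hp <- make_hset(inst$gamma[perm], inst$Gamma[perm], inst$se_Gamma[perm])
  estp <- mr_weighted_median(hp, n_boot = 500, seed = 4)
  expect_equal(est$beta, estp$beta, tolerance = 1e-12)
  # estimate stays near the planted slope 0.3 despite the outlier
  expect_lt(abs(est$beta - 0.3), 3 * est$se)
  expect_warning(mr_weighted_median(h, n_boot = 50, seed = 1),
                 "fewer than 100")
})

test_that("estimators are equivariant under outcome sign flip", {
  inst <- random_instance(k = 15, seed = 8)
  h <- make_hset(inst$gamma, inst$Gamma, inst$se_Gamma)
  hneg <- make_hset(inst$gamma, -inst$Gamma, inst$se_Gamma)
  for (mode in c("fixed", "multiplicative_random")) {
    a <- mr_ivw(h, mode = mode); b <- mr_ivw(hneg, mode = mode)
    expect_equal(b$beta, -a$beta, tolerance = 1e-12)
    expect_equal(b$se, a$se, tolerance = 1e-12)
  }
  ea <- mr_egger(h); eb <- mr_egger(hneg)
  expect_equal(eb$slope$beta, -ea$slope$beta, tolerance = 1e-12)
  expect_equal(eb$intercept, -ea$intercept, tolerance = 1e-12)
  expect_equal(eb$slope$se, ea$slope$se, tolerance = 1e-12)
  wa <- mr_weighted_median(h, n_boot = 1000, seed = 5)
  wb <- mr_weighted_median(hneg, n_boot = 1000, seed = 5)
  expect_equal(wb$beta, -wa$beta, tolerance = 1e-12)
  # the bootstrap SE is equal in distribution (not draw-by-draw) under flip
  expect_equal(wb$se, wa$se, tolerance = 0.15)
})

test_that("IVW recovers the true effect on clean synthetic data", {
  hits <- vapply(1:40, function(r) {
    st <- simulate_study(sim_config(n_snps_exposure = 100,
                                    n_snps_mediator = 0, alpha_true = 0,
                                    theta_direct = -0.19, seed = 500 + r))
    iv <- select_instruments(st$exposure_stats)
    est <- mr_ivw(harmonize(iv, st$outcome_stats))
    abs(est$beta - st$truth$total) < 3 * est$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
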
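est <- function(beta, se = 0.05) mr_estimate("ivw_mre", beta, se, 10L)

test_that("product-of-coefficients indirect effect and its delta SE", {
  # worked values from a published dietary-habits mediation analysis:
  # alpha = -0.440, beta2* = 0.190 -> indirect -0.0836 (prints as -0.084)
  ind <- indirect_effect(est(-0.440, 0.072), est(0.190, 0.035))
  expect_equal(ind$beta, -0.0836, tolerance = 1e-12)
  expect_equal(ind$se,
               sqrt(0.440^2 * 0.035^2 + 0.190^2 * 0.072^2), tolerance = 1e-12)
  # alpha = 0.162, beta2* = 0.290 -> 0.04698 (prints as 0.047)
  expect_equal(indirect_effect(est(0.162), est(0.290))$beta, 0.04698,
               tolerance = 1e-12)
  expect_equal(indirect_effect(est(0), est(0.3))$beta, 0)
  # bootstrap SE agrees with the delta method on a well-conditioned case
  b <- indirect_effect(est(-0.44, 0.07), est(0.19, 0.03),
                       method = "bootstrap", n_boot = 20000, seed = 2)
  d <- indirect_effect(est(-0.44, 0.07), est(0.19, 0.03))
  expect_equal(b$se, d$se, tolerance = 0.05)
})

test_that("proportion mediated is the indirect/total ratio with a delta CI", {
  pm <- proportion_mediated(est(-0.084, 0.003), est(-0.275, 0.093))
  expect_equal(pm$pm, -0.084 / -0.275, tolerance = 1e-12)
  v <- 0.003^2 / 0.275^2 + 0.084^2 * 0.093^2 / 0.275^4
  expect_equal(pm$se, sqrt(v), tolerance = 1e-12)
  expect_equal(pm$ci_low, pm$pm - qnorm(0.975) * pm$se, tolerance = 1e-10)
  expect_false(pm$outside_unit)
  expect_true(pm$consistent)

  expect_equal(proportion_mediated(est(0.3), est(0.3))$pm, 1)
  expect_error(proportion_mediated(est(0.1), est(0)),
               class = "mr_undefined_proportion_error")
  # inconsistent mediation is flagged and reported, not suppressed
  expect_warning(pmi <- proportion_mediated(est(0.05), est(-0.2)),
                 "inconsistent")
  expect_false(pmi$consistent)
  expect_true(pmi$outside_unit)
  expect_equal(pmi$pm, -0.25)
})

test_that("proportion mediated is invariant to rescaling the mediator's units", {
  a <- est(-0.44, 0.07); b2 <- est(0.19, 0.035); tot <- est(-0.2736, 0.02)
  pm0 <- proportion_mediated(indirect_effect(a, b2), tot)
  c_ <- 3.7
  a2 <- est(a$beta * c_, a$se * c_)
  b22 <- est(b2$beta / c_, b2$se / c_)
  pm1 <- proportion_mediated(indirect_effect(a2, b22), tot)
  expect_equal(pm1$pm, pm0$pm, tolerance = 1e-12)
})

test_that("two-step legs estimate the structural path coefficients", {
  st <- simulate_study(sim_config(seed = 61))
  ts <- two_step_effects(st$exposure_stats, st$mediator_stats,
                         st$outcome_stats)
  expect_lt(abs(ts$alpha$beta - (-0.44)), 3 * ts$alpha$se)
  expect_lt(abs(ts$total_beta1$beta - st$truth$total), 3 * ts$total_beta1$se)
  # the mediator's instrument list inevitably picks up exposure SNPs whose
  # mediator association (alpha*gamma) reaches significance; through those
  # SNPs the ratio is total/alpha rather than beta2, so the univariable
  # beta2 leg is attenuated toward it — the reason the indirect effect uses
  # the MVMR direct effect beta2* instead
  expect_true(ts$beta2$beta > 0.19 - 3 * ts$beta2$se &&
                ts$beta2$beta < st$truth$total / -0.44 + 3 * ts$beta2$se)

  # a mediator generated independently of the exposure gives alpha near 0
  # and an uncontaminated beta2 leg that recovers the planted effect,
  # so total = direct + alpha*beta2 reduces to the direct effect
  st0 <- simulate_study(sim_config(alpha_true = 0, seed = 62))
  ts0 <- two_step_effects(st0$exposure_stats, st0$mediator_stats,
                          st0$outcome_stats)
  expect_lt(abs(ts0$alpha$beta), 3 * ts0$alpha$se)
  expect_lt(abs(ts0$beta2$beta - 0.19), 3 * ts0$beta2$se)
  expect_lt(abs(ts0$total_beta1$beta - (-0.19)), 3 * ts0$total_beta1$se)
})

test_that("mediate ties the decomposition together consistently", {
  st <- simulate_study(sim_config(seed = 63))
  med <- mediate(st$exposure_stats, st$mediator_stats, st$outcome_stats)
  p <- med$per_mediator$mediator
  # internal identity: PM = indirect / total to full precision
  expect_equal(p$pm$pm, p$indirect$beta / med$total_beta1$beta,
               tolerance = 1e-12)
  expect_equal(p$indirect$beta, p$alpha$beta * p$beta2_star$beta,
               tolerance = 1e-12)
  # the decomposition recovers the generating truth
  expect_lt(abs(p$pm$pm - st$truth$pm_true), qnorm(0.975) * p$pm$se)
  tab <- as.data.frame(med)
  expect_equal(tab$proportion_mediated, p$pm$pm)
  expect_true(all(c("beta1_star", "beta2_star", "indirect", "alpha",
                    "beta2") %in% names(tab)))
})

test_that("a second true mediator attenuates the joint direct effect", {
  # hand-built two-mediator linear model: each trait instrumented by its
  # own 20 SNPs, outcome effects composed along both mediated paths
  set.seed(66)
  k <- 60
  grp <- rep(c("x", "m1", "m2"), each = 20)
  draw <- function(on) ifelse(grp == on,
                              sample(c(-1, 1), k, TRUE) * runif(k, 0.03, 0.09),
                              0)
  g <- draw("x"); d1 <- draw("m1"); d2 <- draw("m2")
  theta <- -0.1; a1 <- -0.4; b1 <- 0.2; a2 <- 0.5; b2 <- -0.2
  m1_true <- a1 * g + d1
  m2_true <- a2 * g + d2
  y_true <- theta * g + b1 * m1_true + b2 * m2_true
  se <- 0.004
  rsid <- sprintf("rs%03d", 1:k)
  mk <- function(truth, nm) {
    make_stats(rsid, truth + rnorm(k, 0, se), rep(se, k), trait_name = nm)
  }
  ex <- mk(g, "exposure"); m1 <- mk(m1_true, "m1"); m2 <- mk(m2_true, "m2")
  ou <- mk(y_true, "outcome")
  med1 <- mediate(ex, m1, ou)
  med2 <- suppressWarnings(mediate(ex, list(m1, m2), ou))
  expect_false(is.null(med2$joint))
  # single-mediator direct effect still carries the unmodelled second path
  # (theta + a2*b2 = -0.2); the joint model strips it back to theta
  expect_lt(abs(med2$joint$direct_exposure$beta),
            abs(med1$per_mediator$m1$beta1_star$beta))
  expect_lt(abs(med2$joint$direct_exposure$beta - theta),
            3 * med2$joint$direct_exposure$se)
  # the combined indirect effect is the sum of the per-mediator products
  parts <- vapply(med2$joint$indirect_per_mediator, function(x) x$beta,
                  numeric(1))
  expect_equal(med2$joint$indirect_combined$beta, sum(parts),
               tolerance = 1e-12)
  expect_equal(med2$joint$pm_combined$pm,
               sum(parts) / med2$total_beta1$beta, tolerance = 1e-12)
  # truth PM for the joint model: (a1*b1 + a2*b2) / total
  pm_true <- (a1 * b1 + a2 * b2) / (theta + a1 * b1 + a2 * b2)
  expect_lt(abs(med2$joint$pm_combined$pm - pm_true),
            qnorm(0.995) * med2$joint$pm_combined$se)
})
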
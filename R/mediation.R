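# Two-step MR + MVMR mediation: decompose the total effect of an exposure
# on an outcome into a direct path and a path through one or more mediators,
# with product-of-coefficients indirect effects and proportions mediated.

#' Default analysis settings shared by the mediation and pipeline layers
#'
#' @param p_threshold genome-wide significance threshold for instruments.
#' @param r2_max,window_kb clumping rules.
#' @param f_min minimum instrument F statistic.
#' @param palindrome_eaf_window harmonization ambiguity window.
#' @param ivw_mode \code{"multiplicative_random"} or \code{"fixed"}.
#' @param n_boot weighted-median bootstrap replicates.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param alpha_level significance level for flags.
#' @param seed integer seed used by every stochastic stage.
#' @return A named list of settings.
#' @export
mr_config <- function(p_threshold = 5e-8, r2_max = 0.001, window_kb = 10000,
                      f_min = 10, palindrome_eaf_window = 0.08,
                      ivw_mode = "multiplicative_random", n_boot = 1000,
                      presso_n_sim = 1000, alpha_level = 0.05, seed = 1L) {
  list(p_threshold = p_threshold, r2_max = r2_max, window_kb = window_kb,
       f_min = f_min, palindrome_eaf_window = palindrome_eaf_window,
       ivw_mode = ivw_mode, n_boot = n_boot, presso_n_sim = presso_n_sim,
       alpha_level = alpha_level, seed = as.integer(seed))
}

select_with_config <- function(stats, config) {
  select_instruments(stats, p_threshold = config$p_threshold,
                     r2_max = config$r2_max, window_kb = config$window_kb,
                     f_min = config$f_min)
}

leg_estimate <- function(instruments, target_stats, config, leg) {
  h <- tryCatch(
    harmonize(instruments, target_stats, config$palindrome_eaf_window),
    error = function(e) {
      mr_error(sprintf("mediation leg '%s' failed: %s", leg,
                       conditionMessage(e)), "mr_mediation_leg_error")
    }
  )
  est <- mr_ivw(h, mode = config$ivw_mode)
  attr(est, "harmonized") <- h
  est
}

#' Two-step MR effects for one exposure/mediator/outcome triad
#'
#' Estimates, by the configured univariable estimator (IVW), the three
#' legs of the two-step design: the total effect of the exposure on the
#' outcome (beta1, from the exposure's instruments), the effect of the
#' exposure on the mediator (alpha, same instruments), and the univariable
#' effect of the mediator on the outcome (beta2, from the mediator's own
#' instruments). The design assumes no exposure-mediator interaction.
#'
#' @param exposure,mediator,outcome \code{summary_stats} objects.
#' @param config settings from \code{\link{mr_config}}.
#' @return List with \code{total_beta1}, \code{alpha}, \code{beta2}
#'   (\code{mr_estimate}s) and the two instrument sets
#'   (\code{exposure_instruments}, \code{mediator_instruments}).
#' @export
two_step_effects <- function(exposure, mediator, outcome,
                             config = mr_config()) {
  exp_iv <- select_with_config(exposure, config)
  med_iv <- select_with_config(mediator, config)
  list(
    total_beta1 = leg_estimate(exp_iv, outcome, config, "exposure->outcome"),
    alpha = leg_estimate(exp_iv, mediator, config, "exposure->mediator"),
    beta2 = leg_estimate(med_iv, outcome, config, "mediator->outcome"),
    exposure_instruments = exp_iv,
    mediator_instruments = med_iv
  )
}

#' Product-of-coefficients indirect effect
#'
#' The mediated effect \eqn{\alpha \times \beta_2^*}: the exposure's effect
#' on the mediator times the mediator's direct effect on the outcome
#' conditional on the exposure. The standard error uses the two-sample
#' delta method with zero covariance,
#' \eqn{\sqrt{\alpha^2 SE_{\beta_2^*}^2 + \beta_2^{*2} SE_\alpha^2}},
#' appropriate when the two estimates come from non-overlapping
#' regressions; a seeded parametric bootstrap is available instead.
#'
#' @param alpha \code{mr_estimate} (or list with \code{beta}, \code{se}) for
#'   the exposure-to-mediator effect.
#' @param beta2_star same, for the mediator's direct effect on the outcome.
#' @param method \code{"delta"} (default) or \code{"bootstrap"}.
#' @param n_boot,seed bootstrap controls (used when
#'   \code{method = "bootstrap"}).
#' @return An \code{mr_estimate} with method \code{"indirect_product"}.
#' @export
indirect_effect <- function(alpha, beta2_star, method = c("delta", "bootstrap"),
                            n_boot = 5000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.finite(alpha$beta), is.finite(beta2_star$beta))
  point <- alpha$beta * beta2_star$beta
  se <- if (method == "delta") {
    sqrt(alpha$beta^2 * beta2_star$se^2 + beta2_star$beta^2 * alpha$se^2)
  } else {
    with_seed(seed, {
      stats::sd(stats::rnorm(n_boot, alpha$beta, alpha$se) *
                  stats::rnorm(n_boot, beta2_star$beta, beta2_star$se))
    })
  }
  mr_estimate("indirect_product", point, se, NA_integer_)
}

#' Proportion of the total effect that is mediated
#'
#' \eqn{PM = (\alpha \times \beta_2^*) / \beta_1}: the indirect effect as a
#' fraction of the total effect. The confidence interval comes from the
#' first-order delta method on the ratio with zero cross-covariance:
#' \eqn{Var(PM) = Var(ind)/\beta_1^2 + ind^2 Var(\beta_1)/\beta_1^4}.
#' Estimates outside \eqn{[0,1]} — including inconsistent mediation, where
#' indirect and total effects have opposite signs — are reported as-is and
#' flagged, never clipped or suppressed.
#'
#' @param indirect \code{mr_estimate} for the indirect effect.
#' @param total_beta1 \code{mr_estimate} for the total effect (nonzero).
#' @return A \code{pm_estimate}: list with \code{pm}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{consistent} (indirect and total
#'   share sign) and \code{outside_unit} flags.
#' @export
proportion_mediated <- function(indirect, total_beta1) {
  if (total_beta1$beta == 0) {
    mr_error("total effect is zero: proportion mediated undefined",
             "mr_undefined_proportion_error")
  }
  pm <- indirect$beta / total_beta1$beta
  v <- indirect$se^2 / total_beta1$beta^2 +
    indirect$beta^2 * total_beta1$se^2 / total_beta1$beta^4
  se <- sqrt(v)
  consistent <- sign(indirect$beta) == sign(total_beta1$beta) ||
    indirect$beta == 0
  if (!consistent) {
    warning("inconsistent mediation: indirect and total effects have opposite signs")
  }
  structure(
    list(pm = pm, se = se, ci_low = pm - Z95 * se, ci_high = pm + Z95 * se,
         consistent = consistent, outside_unit = pm < 0 || pm > 1),
    class = "pm_estimate"
  )
}

#' @export
print.pm_estimate <- function(x, ...) {
  cat(sprintf(
    "Proportion mediated = %.3f (95%% CI %.3f to %.3f)%s%s\n",
    x$pm, x$ci_low, x$ci_high,
    if (!x$consistent) "  [inconsistent mediation]" else "",
    if (x$outside_unit) "  [outside 0-1]" else ""
  ))
  invisible(x)
}

#' Full mediation analysis for one exposure, one or more mediators, one outcome
#'
#' Runs the complete decomposition: two-step MR for the total effect
#' (beta1), exposure-to-mediator effects (alpha) and univariable
#' mediator-to-outcome effects (beta2); a per-mediator multivariable model
#' giving the controlled direct effects of exposure (beta1*) and mediator
#' (beta2*); the product-of-coefficients indirect effect
#' \eqn{\alpha \times \beta_2^*}; and the proportion mediated. With two or
#' more mediators a joint multivariable model is also fitted, whose
#' combined proportion mediated is
#' \eqn{\sum_i \alpha_i \beta_{2i}^{*(joint)} / \beta_1}.
#'
#' @param exposure a \code{summary_stats} object.
#' @param mediators a single \code{summary_stats} or a list of them.
#' @param outcome a \code{summary_stats} object.
#' @param config settings from \code{\link{mr_config}}.
#' @return A \code{mediation_result}: list with \code{exposure},
#'   \code{mediators}, \code{outcome}, \code{total_beta1}, and per-mediator
#'   records (\code{alpha}, \code{beta2}, \code{beta1_star},
#'   \code{beta2_star}, \code{indirect}, \code{pm}); plus \code{joint}
#'   (direct effects, combined indirect and PM) when several mediators are
#'   supplied. \code{as.data.frame} renders the mediation report table.
#' @export
mediate <- function(exposure, mediators, outcome, config = mr_config()) {
  if (inherits(mediators, "summary_stats")) mediators <- list(mediators)
  stopifnot(length(mediators) >= 1, inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  med_names <- vapply(mediators, function(m) m$trait_name, character(1))

  exp_iv <- select_with_config(exposure, config)
  total <- leg_estimate(exp_iv, outcome, config, "exposure->outcome")

  per_med <- lapply(seq_along(mediators), function(i) {
    med <- mediators[[i]]
    med_iv <- select_with_config(med, config)
    alpha <- leg_estimate(exp_iv, med, config, sprintf("exposure->%s", med_names[i]))
    beta2 <- leg_estimate(med_iv, outcome, config, sprintf("%s->outcome", med_names[i]))
    mv <- build_mv_set(list(exp_iv, med_iv), list(exposure, med), outcome,
                       window_kb = config$window_kb, r2_max = config$r2_max,
                       palindrome_eaf_window = config$palindrome_eaf_window)
    fit <- mvmr_ivw(mv)
    beta1_star <- fit$estimates[[exposure$trait_name]]
    beta2_star <- fit$estimates[[med$trait_name]]
    ind <- indirect_effect(alpha, beta2_star)
    pm <- proportion_mediated(ind, total)
    list(mediator = med_names[i], instruments = med_iv, alpha = alpha,
         beta2 = beta2, beta1_star = beta1_star, beta2_star = beta2_star,
         indirect = ind, pm = pm, mvmr = fit)
  })
  names(per_med) <- med_names

  joint <- NULL
  if (length(mediators) >= 2) {
    ivs <- c(list(exp_iv), lapply(per_med, function(p) p$instruments))
    stats_list <- c(list(exposure), mediators)
    mv <- build_mv_set(ivs, stats_list, outcome,
                       window_kb = config$window_kb, r2_max = config$r2_max,
                       palindrome_eaf_window = config$palindrome_eaf_window)
    fit <- mvmr_ivw(mv)
    inds <- lapply(med_names, function(nm) {
      indirect_effect(per_med[[nm]]$alpha, fit$estimates[[nm]])
    })
    comb_beta <- sum(vapply(inds, function(x) x$beta, numeric(1)))
    comb_se <- sqrt(sum(vapply(inds, function(x) x$se^2, numeric(1))))
    comb <- mr_estimate("indirect_combined", comb_beta, comb_se, NA_integer_)
    joint <- list(mvmr = fit,
                  direct_exposure = fit$estimates[[exposure$trait_name]],
                  indirect_per_mediator = stats::setNames(inds, med_names),
                  indirect_combined = comb,
                  pm_combined = proportion_mediated(comb, total))
  }
  structure(
    list(exposure = exposure$trait_name, mediators = med_names,
         outcome = outcome$trait_name, total_beta1 = total,
         per_mediator = per_med, joint = joint, config = config),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: %s -> [%s] -> %s\n", x$exposure,
              paste(x$mediators, collapse = ", "), x$outcome))
  cat(sprintf("  total effect beta1 = %.4g (SE %.4g, p = %.3g)\n",
              x$total_beta1$beta, x$total_beta1$se, x$total_beta1$pval))
  for (p in x$per_mediator) {
    cat(sprintf(
      "  via %s: alpha = %.4g, beta2* = %.4g, indirect = %.4g (SE %.4g), PM = %.3f\n",
      p$mediator, p$alpha$beta, p$beta2_star$beta, p$indirect$beta,
      p$indirect$se, p$pm$pm
    ))
  }
  if (!is.null(x$joint)) {
    cat(sprintf("  joint model: combined indirect = %.4g, combined PM = %.3f\n",
                x$joint$indirect_combined$beta, x$joint$pm_combined$pm))
  }
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  rows <- lapply(x$per_mediator, function(p) {
    data.frame(
      outcome = x$outcome, exposure = x$exposure, intermediator = p$mediator,
      beta1_star = p$beta1_star$beta, beta1_star_se = p$beta1_star$se,
      beta2_star = p$beta2_star$beta, beta2_star_se = p$beta2_star$se,
      alpha = p$alpha$beta, alpha_se = p$alpha$se,
      beta2 = p$beta2$beta, beta2_se = p$beta2$se,
      indirect = p$indirect$beta, indirect_se = p$indirect$se,
      indirect_pval = p$indirect$pval,
      total_beta1 = x$total_beta1$beta,
      proportion_mediated = p$pm$pm,
      pm_ci_low = p$pm$ci_low, pm_ci_high = p$pm$ci_high,
      consistent = p$pm$consistent,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
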
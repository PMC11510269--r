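# Univariable two-sample MR estimators. Throughout, gamma denotes the
# SNP-exposure effects and Gamma the SNP-outcome effects of a harmonized set.

check_hset <- function(h, min_snps, caller) {
  stopifnot(inherits(h, "harmonized_set"))
  k <- nrow(h$data)
  if (k < min_snps) {
    mr_error(sprintf("%s requires at least %d SNPs, got %d",
                     caller, min_snps, k), "mr_insufficient_instruments_error")
  }
  k
}

#' Wald ratio estimate from a single SNP
#'
#' The per-SNP causal estimate \eqn{\Gamma/\gamma} with first-order
#' delta-method standard error \eqn{|SE_\Gamma / \gamma|}. The second-order
#' term, which adds \eqn{\Gamma^2 SE_\gamma^2 / \gamma^4} to the variance,
#' is available but off by default.
#'
#' @param gamma SNP-exposure effect (nonzero).
#' @param se_gamma its standard error.
#' @param Gamma SNP-outcome effect.
#' @param se_Gamma its standard error.
#' @param rsid optional identifier used in error messages.
#' @param second_order include the second-order delta-method variance term.
#' @return An \code{mr_estimate} with method \code{"wald"}.
#' @export
mr_wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma,
                          rsid = NULL, second_order = FALSE) {
  if (gamma == 0) {
    mr_error(sprintf("zero SNP-exposure effect%s: Wald ratio undefined",
                     if (is.null(rsid)) "" else paste0(" for ", rsid)),
             "mr_division_error")
  }
  beta <- Gamma / gamma
  v <- (se_Gamma / gamma)^2
  if (second_order) v <- v + Gamma^2 * se_gamma^2 / gamma^4
  mr_estimate("wald", beta, sqrt(v), 1L)
}

ivw_core <- function(gamma, Gamma, se_Gamma) {
  w <- 1 / se_Gamma^2
  sxx <- sum(w * gamma^2)
  beta <- sum(w * gamma * Gamma) / sxx
  list(beta = beta, se_fe = sqrt(1 / sxx), w = w, sxx = sxx)
}

#' Inverse-variance-weighted causal estimate
#'
#' The primary two-sample MR estimator: the slope of the zero-intercept
#' weighted least-squares regression of outcome on exposure associations
#' with weights \eqn{1/SE_\Gamma^2}, in closed form
#' \deqn{\hat\beta = \sum_j w_j \gamma_j \Gamma_j / \sum_j w_j \gamma_j^2.}
#' The fixed-effect standard error is \eqn{(\sum_j w_j\gamma_j^2)^{-1/2}};
#' the multiplicative-random-effects mode (default) inflates it by
#' \eqn{\max(1, \sqrt{Q/(k-1)})} with Q the Cochran heterogeneity statistic,
#' so the two modes coincide when \eqn{Q \le k-1}. P-values are two-sided
#' normal.
#'
#' @param h a \code{harmonized_set} with at least 2 SNPs.
#' @param mode \code{"multiplicative_random"} (default) or \code{"fixed"}.
#' @return An \code{mr_estimate} (method \code{"ivw_mre"} or
#'   \code{"ivw_fe"}) carrying Cochran's Q and its p-value.
#' @export
mr_ivw <- function(h, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  k <- check_hset(h, 2L, "IVW")
  d <- h$data
  core <- ivw_core(d$beta_exposure, d$beta_outcome, d$se_outcome)
  q <- sum(core$w * (d$beta_outcome - core$beta * d$beta_exposure)^2)
  q_pval <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  se <- if (mode == "fixed") {
    core$se_fe
  } else {
    core$se_fe * max(1, sqrt(q / (k - 1)))
  }
  mr_estimate(if (mode == "fixed") "ivw_fe" else "ivw_mre",
              core$beta, se, k, q = q, q_pval = q_pval)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure associations with an
#' unconstrained intercept (weights \eqn{1/SE_\Gamma^2}), after orienting
#' all SNP-exposure effects to be non-negative. The intercept estimates the
#' average directional pleiotropic effect: an intercept p-value below
#' \code{alpha_level} flags horizontal pleiotropy. Standard errors use the
#' multiplicative random-effects scaling \eqn{\max(1, \hat\sigma)} with
#' \eqn{\hat\sigma^2} the weighted residual mean square on \eqn{k-2}
#' degrees of freedom; p-values are two-sided normal.
#'
#' @param h a \code{harmonized_set} with at least 3 SNPs.
#' @param alpha_level significance level for the pleiotropy flag.
#' @return An \code{egger_estimate}: list with \code{slope} (an
#'   \code{mr_estimate}, method \code{"egger_slope"}), \code{intercept},
#'   \code{intercept_se}, \code{intercept_pval} and \code{pleiotropy_flag}.
#' @export
mr_egger <- function(h, alpha_level = 0.05) {
  k <- check_hset(h, 3L, "MR-Egger")
  d <- h$data
  flip <- sign(d$beta_exposure)
  flip[flip == 0] <- 1
  x <- d$beta_exposure * flip
  y <- d$beta_outcome * flip
  w <- 1 / d$se_outcome^2
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sy - slope * sx) / sw
  rss <- sum(w * (y - intercept - slope * x)^2)
  sigma <- sqrt(rss / (k - 2))
  infl <- max(1, sigma)
  se_slope <- sqrt(sw / det) * infl
  se_int <- sqrt(sxx / det) * infl
  int_p <- ztop(intercept / se_int)
  est <- mr_estimate("egger_slope", slope, se_slope, k)
  structure(
    list(slope = est, intercept = intercept, intercept_se = se_int,
         intercept_pval = int_p, pleiotropy_flag = int_p < alpha_level),
    class = "egger_estimate"
  )
}

#' @export
print.egger_estimate <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.4g (SE %.4g, p = %.3g)%s\n",
              x$intercept, x$intercept_se, x$intercept_pval,
              if (x$pleiotropy_flag) "  [pleiotropy flagged]" else ""))
  invisible(x)
}

weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  # midpoint cumulative weights: s_j = cumsum(w)_j - w_j/2; the estimate is
  # the value where s crosses 0.5, linearly interpolated, which reduces to
  # the ordinary median under equal weights
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios, consistent when SNPs
#' carrying at least half of the weight are valid instruments. Ratios are
#' sorted ascending with inverse-variance weights
#' \eqn{w_j = \gamma_j^2 / SE_{\Gamma j}^2} normalized to sum one; the
#' estimate is the ratio at which the midpoint cumulative weight crosses
#' 0.5, linearly interpolated. The standard error comes from a parametric
#' bootstrap: each replicate redraws \eqn{\gamma_j} and \eqn{\Gamma_j} from
#' normal distributions centred on the observed values with their reported
#' SEs and recomputes the weighted median.
#'
#' @param h a \code{harmonized_set} with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000; below 100 a warning is
#'   issued).
#' @param seed integer seed for the bootstrap, mandatory for
#'   reproducibility.
#' @return An \code{mr_estimate} with method \code{"weighted_median"}.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  k <- check_hset(h, 3L, "weighted median")
  if (missing(seed)) mr_error("a bootstrap seed is required", "mr_config_error")
  if (n_boot < 100) {
    warning("fewer than 100 bootstrap replicates: SE will be unstable")
  }
  d <- h$data
  ratios <- d$beta_outcome / d$beta_exposure
  weights <- d$beta_exposure^2 / d$se_outcome^2
  point <- weighted_median_point(ratios, weights)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      g <- stats::rnorm(k, d$beta_exposure, d$se_exposure)
      G <- stats::rnorm(k, d$beta_outcome, d$se_outcome)
      weighted_median_point(G / g, g^2 / d$se_outcome^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", point, stats::sd(boots), k)
}

#' Run the full univariable estimator battery on one harmonized pair
#'
#' @param h a \code{harmonized_set}.
#' @param mode IVW mode passed to \code{\link{mr_ivw}}.
#' @param n_boot,seed weighted-median bootstrap controls.
#' @return A data frame with one row per method in the forest-plot shape:
#'   exposure, outcome, method, n_snp, beta, se, ci_low, ci_high, pval.
#' @export
mr_all_methods <- function(h, mode = "multiplicative_random",
                           n_boot = 1000, seed) {
  ests <- list(mr_ivw(h, mode = mode))
  if (nrow(h$data) >= 3) {
    ests <- c(ests, list(mr_egger(h)$slope,
                         mr_weighted_median(h, n_boot = n_boot, seed = seed)))
  }
  tab <- do.call(rbind, lapply(ests, as.data.frame))
  tab <- cbind(exposure = h$exposure_name, outcome = h$outcome_name,
               tab[, c("method", "n_snp", "beta", "se",
                       "ci_low", "ci_high", "pval")])
  rownames(tab) <- NULL
  tab
}
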
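# Heterogeneity and horizontal-pleiotropy diagnostics.

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_j w_j (\hat\beta_j - \hat\beta_{IVW})^2} over the per-SNP
#' Wald ratios \eqn{\hat\beta_j = \Gamma_j/\gamma_j}, with first-order
#' weights \eqn{w_j = \gamma_j^2/SE_{\Gamma j}^2} and
#' \eqn{\hat\beta_{IVW}} the fixed-effect IVW estimate. Smaller p-values
#' (upper tail of \eqn{\chi^2_{k-1}}) indicate greater heterogeneity and a
#' higher potential for directional pleiotropy.
#'
#' @param h a \code{harmonized_set} with at least 2 SNPs.
#' @return A \code{q_result}: list with \code{q}, \code{df} and \code{pval};
#'   the per-SNP contributions are attached as attribute
#'   \code{"contributions"}.
#' @export
cochran_q <- function(h) {
  k <- check_hset(h, 2L, "Cochran's Q")
  d <- h$data
  ratios <- d$beta_outcome / d$beta_exposure
  w <- d$beta_exposure^2 / d$se_outcome^2
  beta_fe <- sum(w * ratios) / sum(w)
  contrib <- w * (ratios - beta_fe)^2
  q <- sum(contrib)
  res <- structure(
    list(q = q, df = k - 1L,
         pval = stats::pchisq(q, df = k - 1, lower.tail = FALSE)),
    class = "q_result"
  )
  attr(res, "contributions") <- stats::setNames(contrib, d$rsid)
  res
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

# Leave-one-out fixed-effect IVW slopes for all j at once, from running sums.
loo_ivw_slopes <- function(gamma, Gamma, w) {
  sxy <- sum(w * gamma * Gamma)
  sxx <- sum(w * gamma^2)
  (sxy - w * gamma * Gamma) / (sxx - w * gamma^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of pleiotropic outlier SNPs, in three parts.
#' \emph{Global test}: the observed residual sum of squares
#' \eqn{RSS = \sum_j w_j (\Gamma_j - \gamma_j \hat\beta^{(-j)})^2}, with
#' \eqn{w_j = 1/SE_{\Gamma j}^2} and \eqn{\hat\beta^{(-j)}} the
#' leave-one-out fixed-effect IVW slope, is compared against its null
#' distribution built by simulating
#' \eqn{\Gamma^*_j \sim N(\gamma_j\hat\beta^{(-j)}, SE_{\Gamma j})} and
#' \eqn{\gamma^*_j \sim N(\gamma_j, SE_{\gamma j})} \code{n_sim} times and
#' recomputing RSS on each replicate with its own leave-one-out slopes; the
#' empirical p-value uses the plus-one rule
#' \eqn{(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)} and so never reaches zero.
#' \emph{Outlier test}: each SNP's observed weighted squared residual gets
#' an empirical p against its own simulated distribution,
#' Bonferroni-corrected across the k SNPs; SNPs whose corrected p falls
#' below \code{significance} are flagged. \emph{Distortion test}: the shift
#' between the raw IVW estimate and the estimate after removing flagged
#' outliers is compared against the null shift obtained by removing
#' equally many SNPs at random (\code{n_distortion} subsets); skipped when
#' no outlier is flagged.
#'
#' @param h a \code{harmonized_set} with at least 4 SNPs.
#' @param n_sim number of simulated replicates (1000 or more recommended).
#' @param significance outlier significance threshold applied to the
#'   Bonferroni-corrected per-SNP p (default 0.05).
#' @param seed integer seed; results are reproducible for a fixed seed and
#'   \code{n_sim}.
#' @param n_distortion random subsets used by the distortion test.
#' @param mode IVW mode for the raw/corrected estimates.
#' @return A \code{presso_result}: list with \code{rss_obs},
#'   \code{global_pval}, \code{outliers} (data frame rsid, raw and
#'   Bonferroni-corrected p), \code{distortion_pval} (NA when skipped),
#'   \code{beta_raw}, \code{beta_corrected} (NULL when nothing removed),
#'   \code{n_sim}, \code{seed}.
#' @export
mr_presso <- function(h, n_sim = 1000, significance = 0.05, seed,
                      n_distortion = 1000, mode = "multiplicative_random") {
  k <- check_hset(h, 4L, "MR-PRESSO")
  if (missing(seed)) mr_error("a simulation seed is required", "mr_config_error")
  d <- h$data
  w <- 1 / d$se_outcome^2
  b_loo <- loo_ivw_slopes(d$beta_exposure, d$beta_outcome, w)
  r_obs <- w * (d$beta_outcome - d$beta_exposure * b_loo)^2
  rss_obs <- sum(r_obs)

  sim <- with_seed(seed, {
    # k x n_sim matrices of simulated associations under the no-pleiotropy
    # expectation of each SNP
    Gs <- matrix(stats::rnorm(k * n_sim, mean = d$beta_exposure * b_loo,
                              sd = d$se_outcome), nrow = k)
    gs <- matrix(stats::rnorm(k * n_sim, mean = d$beta_exposure,
                              sd = d$se_exposure), nrow = k)
    sxy <- colSums(w * gs * Gs)
    sxx <- colSums(w * gs^2)
    b_loo_s <- (rep(sxy, each = k) - w * gs * Gs) /
      (rep(sxx, each = k) - w * gs^2)
    w * (Gs - gs * b_loo_s)^2   # k x n_sim per-SNP residuals
  })
  rss_sim <- colSums(sim)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_raw <- (1 + rowSums(sim >= r_obs)) / (n_sim + 1)
  p_bonf <- pmin(1, k * p_raw)
  is_out <- p_bonf < significance
  outliers <- data.frame(rsid = d$rsid[is_out], outlier_pval = p_raw[is_out],
                         outlier_pval_bonf = p_bonf[is_out],
                         stringsAsFactors = FALSE)
  if (all(is_out)) {
    mr_error("every SNP was flagged as an outlier; no corrected estimate is possible",
             "mr_degenerate_result_error")
  }
  beta_raw <- mr_ivw(h, mode = mode)
  beta_corrected <- NULL
  distortion_pval <- NA_real_
  if (any(is_out)) {
    h_kept <- h
    h_kept$data <- d[!is_out, , drop = FALSE]
    beta_corrected <- mr_ivw(h_kept, mode = mode)
    n_out <- sum(is_out)
    d_obs <- beta_corrected$beta - beta_raw$beta
    d_sim <- with_seed(seed + 1L, {
      vapply(seq_len(n_distortion), function(b) {
        idx <- sample.int(k, n_out)
        core <- ivw_core(d$beta_exposure[-idx], d$beta_outcome[-idx],
                         d$se_outcome[-idx])
        core$beta - beta_raw$beta
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_distortion + 1)
  } else {
    message("MR-PRESSO: no outliers flagged; distortion test skipped")
  }
  structure(
    list(rss_obs = rss_obs, global_pval = global_pval, outliers = outliers,
         distortion_pval = distortion_pval, beta_raw = beta_raw,
         beta_corrected = beta_corrected, n_sim = n_sim, seed = seed),
    class = "presso_result"
  )
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g, %d outlier(s)\n",
              x$rss_obs, x$global_pval, nrow(x$outliers)))
  if (nrow(x$outliers) > 0) {
    cat(sprintf("  outliers: %s; distortion p = %.3g\n",
                paste(x$outliers$rsid, collapse = ", "), x$distortion_pval))
  }
  invisible(x)
}

ci_excludes_zero <- function(est) est$ci_low > 0 || est$ci_high < 0

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW causal effect k times, omitting each SNP in turn. A
#' row is flagged when omitting that SNP changes the sign of the estimate
#' or moves the 95\% confidence interval across zero relative to the
#' all-SNP estimate, marking the omitted SNP as potentially dominant.
#'
#' @param h a \code{harmonized_set} with at least 3 SNPs.
#' @param mode IVW mode.
#' @return A \code{loo_table}: data frame with one row per omitted SNP
#'   (excluded_rsid, n_snp, beta, se, ci_low, ci_high, pval, flagged); the
#'   all-SNP estimate is attached as attribute \code{"full_estimate"}.
#' @export
leave_one_out <- function(h, mode = "multiplicative_random") {
  k <- check_hset(h, 3L, "leave-one-out")
  full <- mr_ivw(h, mode = mode)
  rows <- lapply(seq_len(k), function(j) {
    hj <- h
    hj$data <- h$data[-j, , drop = FALSE]
    est <- mr_ivw(hj, mode = mode)
    data.frame(
      excluded_rsid = h$data$rsid[j], n_snp = est$n_snps, beta = est$beta,
      se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
      pval = est$pval,
      flagged = sign(est$beta) != sign(full$beta) ||
        ci_excludes_zero(est) != ci_excludes_zero(full),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("loo_table", "data.frame")
  attr(tab, "full_estimate") <- full
  tab
}
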
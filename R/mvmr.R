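# Multivariable MR: joint estimation of the direct (conditional) effects of
# several exposures on one outcome from summary statistics.

#' Assemble a multivariable harmonized set
#'
#' Takes the union of the per-exposure instrument lists (keeping, for an
#' rsid instrumenting several exposures, the record with the lowest
#' association p-value), re-clumps the union jointly with the same
#' distance/LD rules used for univariable selection, and then requires
#' every retained SNP to have an association row in all exposure tables and
#' in the outcome table, harmonized to the instrument record's effect
#' allele. SNPs missing from any table are dropped with reason
#' \code{"missing_in:<trait>"}; harmonization drops carry their usual
#' reasons.
#'
#' @param exposures list of \code{instrument_set} objects (length m >= 2,
#'   unless \code{allow_single} is set for internal reuse).
#' @param exposure_stats list of \code{summary_stats}, one per exposure, in
#'   the same order (full summary statistics, used to look up instrument
#'   associations with every exposure).
#' @param outcome a \code{summary_stats} for the outcome.
#' @param window_kb,r2_max,ld joint re-clumping parameters (see
#'   \code{\link{select_instruments}}).
#' @param palindrome_eaf_window passed to \code{\link{harmonize}}.
#' @param mode \code{"union"} (default, standard MVMR practice: maximizes
#'   conditional identification) or \code{"intersection"} (keep only SNPs
#'   instrumenting every exposure at genome-wide significance).
#' @param allow_single permit m = 1 (used internally).
#' @return An \code{mv_harmonized_set}: list with \code{outcome_name},
#'   \code{exposure_names}, \code{rsid}, k x m matrices
#'   \code{beta_exposure} and \code{se_exposure}, vectors
#'   \code{beta_outcome} and \code{se_outcome}, \code{provenance} (which
#'   exposure's instrument list contributed each SNP) and \code{dropped}.
#' @export
build_mv_set <- function(exposures, exposure_stats, outcome,
                         window_kb = 10000, r2_max = 0.001, ld = NULL,
                         palindrome_eaf_window = 0.08,
                         mode = c("union", "intersection"),
                         allow_single = FALSE) {
  mode <- match.arg(mode)
  m <- length(exposures)
  stopifnot(length(exposure_stats) == m, inherits(outcome, "summary_stats"))
  if (m < 2 && !allow_single) {
    mr_error("multivariable MR needs at least 2 exposures", "mr_config_error")
  }
  exposure_names <- vapply(exposures, function(e) e$trait_name, character(1))

  cand <- do.call(rbind, lapply(seq_len(m), function(i) {
    r <- exposures[[i]]$records
    r$provenance <- exposure_names[i]
    r
  }))
  if (mode == "intersection") {
    counts <- table(cand$rsid)
    cand <- cand[cand$rsid %in% names(counts)[counts == m], , drop = FALSE]
  }
  # one record per rsid: lowest p across contributing traits, then re-clump
  cand <- cand[order(cand$pval, cand$rsid), , drop = FALSE]
  cand <- cand[!duplicated(cand$rsid), , drop = FALSE]
  cand <- cand[clump_keep(cand, window_kb, r2_max, ld), , drop = FALSE]

  ref <- structure(list(trait_name = "mv_reference", trait_type = "continuous",
                        records = cand),
                   class = "instrument_set")
  dropped <- data.frame(rsid = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  aligned <- vector("list", m)
  keep_rsid <- cand$rsid
  for (i in seq_len(m)) {
    missing <- setdiff(keep_rsid, exposure_stats[[i]]$records$rsid)
    if (length(missing) > 0) {
      dropped <- rbind(dropped, data.frame(
        rsid = missing,
        reason = sprintf("missing_in:%s", exposure_names[i]),
        stringsAsFactors = FALSE
      ))
      keep_rsid <- setdiff(keep_rsid, missing)
    }
  }
  missing_out <- setdiff(keep_rsid, outcome$records$rsid)
  if (length(missing_out) > 0) {
    dropped <- rbind(dropped, data.frame(
      rsid = missing_out,
      reason = sprintf("missing_in:%s", outcome$trait_name),
      stringsAsFactors = FALSE
    ))
    keep_rsid <- setdiff(keep_rsid, missing_out)
  }
  ref$records <- ref$records[ref$records$rsid %in% keep_rsid, , drop = FALSE]
  h_out <- harmonize(ref, outcome, palindrome_eaf_window)
  for (i in seq_len(m)) {
    aligned[[i]] <- harmonize(ref, exposure_stats[[i]], palindrome_eaf_window)
    dropped <- rbind(dropped, aligned[[i]]$dropped)
  }
  dropped <- rbind(dropped, h_out$dropped)
  keep_rsid <- Reduce(intersect, c(list(h_out$data$rsid),
                                   lapply(aligned, function(a) a$data$rsid)))
  k <- length(keep_rsid)
  if (k < m + 1) {
    mr_error(sprintf(
      "only %d SNPs survive multivariable assembly; need at least %d",
      k, m + 1
    ), "mr_insufficient_instruments_error")
  }
  beta_exposure <- vapply(aligned, function(a) {
    a$data$beta_outcome[match(keep_rsid, a$data$rsid)]
  }, numeric(k))
  se_exposure <- vapply(aligned, function(a) {
    a$data$se_outcome[match(keep_rsid, a$data$rsid)]
  }, numeric(k))
  beta_exposure <- matrix(beta_exposure, nrow = k,
                          dimnames = list(keep_rsid, exposure_names))
  se_exposure <- matrix(se_exposure, nrow = k,
                        dimnames = list(keep_rsid, exposure_names))
  io <- match(keep_rsid, h_out$data$rsid)
  structure(
    list(outcome_name = outcome$trait_name,
         exposure_names = exposure_names,
         rsid = keep_rsid,
         beta_exposure = beta_exposure,
         se_exposure = se_exposure,
         beta_outcome = h_out$data$beta_outcome[io],
         se_outcome = h_out$data$se_outcome[io],
         provenance = cand$provenance[match(keep_rsid, cand$rsid)],
         dropped = dropped),
    class = "mv_harmonized_set"
  )
}

#' @export
print.mv_harmonized_set <- function(x, ...) {
  cat(sprintf(
    "Multivariable harmonized set: %d SNPs, exposures [%s] -> '%s'\n",
    length(x$rsid), paste(x$exposure_names, collapse = ", "), x$outcome_name
  ))
  invisible(x)
}

#' Multivariable IVW regression
#'
#' Zero-intercept weighted least squares of the outcome associations
#' \eqn{\Gamma_j} on the m columns of exposure associations, with weights
#' \eqn{1/SE_{\Gamma j}^2}. The coefficient vector estimates the direct
#' (conditional) effect of each exposure on the outcome holding the others
#' fixed. Standard errors come from the weighted-regression covariance
#' \eqn{(X^T W X)^{-1}} scaled by the multiplicative overdispersion factor
#' \eqn{\max(1, \sqrt{Q_{mv}/(k-m)})}, mirroring the univariable
#' random-effects convention; with m = 1 the routine reproduces univariable
#' IVW exactly. A conditional F statistic per exposure (weighted
#' instrument-strength diagnostic conditional on the other exposures,
#' ignoring cross-trait sampling covariance) is reported.
#'
#' @param mv an \code{mv_harmonized_set} with at least m + 1 SNPs.
#' @return An \code{mvmr_result}: list with \code{estimates} (named list of
#'   \code{mr_estimate}, method \code{"mvmr_ivw"}, one per exposure),
#'   \code{cond_f}, \code{q_mv} and \code{n_snps}.
#' @export
mvmr_ivw <- function(mv) {
  stopifnot(inherits(mv, "mv_harmonized_set"))
  X <- mv$beta_exposure
  y <- mv$beta_outcome
  k <- nrow(X); m <- ncol(X)
  if (k < m + 1) {
    mr_error("multivariable IVW needs more SNPs than exposures plus one",
             "mr_insufficient_instruments_error")
  }
  zero_col <- colSums(X != 0) == 0
  if (any(zero_col)) {
    warning(sprintf(
      "exposure column(s) %s carry no association signal; their direct effects are undefined",
      paste(colnames(X)[zero_col], collapse = ", ")
    ))
    sub <- mv
    sub$beta_exposure <- X[, !zero_col, drop = FALSE]
    sub$se_exposure <- mv$se_exposure[, !zero_col, drop = FALSE]
    sub$exposure_names <- mv$exposure_names[!zero_col]
    fit <- mvmr_ivw(sub)
    for (nm in mv$exposure_names[zero_col]) {
      fit$estimates[[nm]] <- mr_estimate("mvmr_ivw", NA_real_, NA_real_,
                                         nrow(X))
      fit$cond_f[nm] <- NA_real_
    }
    fit$estimates <- fit$estimates[mv$exposure_names]
    fit$cond_f <- fit$cond_f[mv$exposure_names]
    return(fit)
  }
  w <- 1 / mv$se_outcome^2
  Xw <- X * sqrt(w)
  yw <- y * sqrt(w)
  xtx <- crossprod(Xw)
  cond <- kappa(xtx, exact = TRUE)
  if (!is.finite(cond) || cond > 1e12) {
    mr_error(sprintf(
      "exposure-association columns are collinear (condition number %.3g)",
      cond
    ), "mr_collinearity_error")
  }
  xtx_inv <- solve(xtx)
  beta <- drop(xtx_inv %*% crossprod(Xw, yw))
  resid <- y - drop(X %*% beta)
  q_mv <- sum(w * resid^2)
  infl <- max(1, sqrt(q_mv / (k - m)))
  se <- sqrt(diag(xtx_inv)) * infl
  estimates <- stats::setNames(lapply(seq_len(m), function(i) {
    mr_estimate("mvmr_ivw", unname(beta[i]), unname(se[i]), k)
  }), mv$exposure_names)
  # conditional instrument strength: residual variation in exposure i's
  # associations after projecting out the other exposures, on its own SE
  # scale (cross-trait sampling covariance not available from summary data)
  cond_f <- vapply(seq_len(m), function(i) {
    wi <- 1 / mv$se_exposure[, i]^2
    xi <- X[, i]
    if (m == 1) {
      r <- xi
    } else {
      Z <- X[, -i, drop = FALSE] * sqrt(wi)
      fit_coef <- qr.coef(qr(Z), xi * sqrt(wi))
      r <- xi - drop(X[, -i, drop = FALSE] %*% fit_coef)
    }
    sum(wi * r^2) / (k - m + 1)
  }, numeric(1))
  structure(
    list(estimates = estimates,
         cond_f = stats::setNames(cond_f, mv$exposure_names),
         q_mv = q_mv, n_snps = k),
    class = "mvmr_result"
  )
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable IVW on %d SNPs (Q = %.4g):\n", x$n_snps, x$q_mv))
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    cat(sprintf(
      "  %s: direct beta = %.4g (SE %.4g, 95%% CI %.4g to %.4g), p = %.3g, cond F = %.1f\n",
      nm, e$beta, e$se, e$ci_low, e$ci_high, e$pval, x$cond_f[nm]
    ))
  }
  invisible(x)
}

#' @export
as.data.frame.mvmr_result <- function(x, ...) {
  do.call(rbind, lapply(names(x$estimates), function(nm) {
    e <- x$estimates[[nm]]
    data.frame(exposure = nm, beta_direct = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               n_snp = e$n_snps, cond_f = unname(x$cond_f[nm]),
               stringsAsFactors = FALSE)
  }))
}
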
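#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the random number generator seeded to \code{seed},
#' then restores the caller's RNG state so that library code never perturbs
#' a user's simulation stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# classed errors so callers can distinguish configuration problems from
# degenerate data
mr_error <- function(msg, class) {
  stop(structure(
    class = c(class, "mrmediate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ztop <- function(z) 2 * stats::pnorm(-abs(z))

# 95% normal CI half-width multiplier used throughout
Z95 <- stats::qnorm(0.975)

#' Construct a causal-effect estimate record
#'
#' @param method label of the estimator that produced the estimate.
#' @param beta point estimate (log-odds of outcome per SD of exposure for a
#'   binary outcome).
#' @param se standard error of \code{beta}.
#' @param n_snps number of instruments used.
#' @param q,q_pval optional Cochran's Q heterogeneity statistic and p-value.
#' @return An object of class \code{mr_estimate}: a list with \code{method},
#'   \code{beta}, \code{se}, \code{ci_low}, \code{ci_high}, \code{pval},
#'   \code{n_snps} and, where defined, \code{heterogeneity_q}/\code{q_pval}.
#' @export
mr_estimate <- function(method, beta, se, n_snps, q = NA_real_, q_pval = NA_real_) {
  structure(list(
    method = method,
    beta = beta,
    se = se,
    ci_low = beta - Z95 * se,
    ci_high = beta + Z95 * se,
    pval = ztop(beta / se),
    n_snps = n_snps,
    heterogeneity_q = q,
    q_pval = q_pval
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "MR estimate [%s]: beta = %.4g (SE %.4g, 95%% CI %.4g to %.4g), p = %.3g, %d SNPs\n",
    x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps
  ))
  if (!is.na(x$heterogeneity_q)) {
    cat(sprintf("  Cochran's Q = %.4g (p = %.3g)\n", x$heterogeneity_q, x$q_pval))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(
    method = x$method, beta = x$beta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
    n_snp = x$n_snps, stringsAsFactors = FALSE
  )
}
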
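# Synthetic exposure/mediator/outcome GWAS summary-statistic triads from a
# known linear structural model, so the whole pipeline can be verified at
# desk scale with no external data.

#' Configuration for a simulated three-trait GWAS study
#'
#' The structural model is linear with no interactions: for exposure
#' instrument j with true effect \eqn{\gamma_j}, the mediator's true effect
#' is \eqn{\alpha\gamma_j} and the outcome's is
#' \eqn{(\theta + \beta_2\alpha)\gamma_j} plus any pleiotropic or outlier
#' offset; mediator-specific instruments affect the outcome only through
#' \eqn{\beta_2}. Summary statistics are simulated directly (no
#' individual-level genotypes): the observed effect is the truth plus
#' normal noise with SE \eqn{1/\sqrt{2 N f (1-f)}} for continuous traits
#' and \eqn{1/\sqrt{2 N \phi(1-\phi) f (1-f)}} for the binary outcome with
#' case fraction \eqn{\phi}. The three GWAS draw independent noise (no
#' sample overlap). Defaults mirror a cheese-intake-like exposure, a
#' BMI-like mediator, and an ischemic-stroke-like binary outcome: direct
#' effect -0.19, exposure-to-mediator effect -0.44, mediator-to-outcome
#' effect 0.19 (truth proportion mediated about 0.3055), 100 instruments
#' per trait and GWAS sample sizes of 200,000.
#'
#' @param n_snps_exposure,n_snps_mediator instrument counts per trait.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (at least 1000).
#' @param outcome_type \code{"binary"} (log-odds effects) or
#'   \code{"continuous"}.
#' @param case_fraction case proportion of the binary outcome GWAS (default
#'   0.08, the order of the ischemic-stroke case fraction in large
#'   case-control panels).
#' @param theta_direct direct exposure-to-outcome effect.
#' @param alpha_true exposure-to-mediator effect.
#' @param beta2_true mediator-to-outcome effect.
#' @param pleiotropy_frac fraction of exposure instruments given a direct
#'   outcome effect (horizontal pleiotropy).
#' @param pleiotropy_sd SD of those pleiotropic effects.
#' @param directional_shift mean pleiotropic offset: 0 gives balanced
#'   pleiotropy, nonzero gives directional (InSIDE-violating) pleiotropy.
#' @param n_outliers,outlier_magnitude count of planted gross outliers among
#'   the exposure instruments and their offset in units of the SNP's
#'   outcome SE (default 10).
#' @param eaf_range allele-frequency sampling interval.
#' @param z_range range of true association z-scores for instruments; the
#'   default \eqn{[7, 25]} makes instruments pass genome-wide significance
#'   with high probability and yields F statistics in the tens-to-hundreds
#'   range seen in strong-instrument screens.
#' @param seed mandatory integer seed.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_snps_exposure = 100, n_snps_mediator = 100,
                       n_exposure = 200000, n_mediator = 200000,
                       n_outcome = 200000,
                       outcome_type = c("binary", "continuous"),
                       case_fraction = 0.08,
                       theta_direct = -0.19, alpha_true = -0.44,
                       beta2_true = 0.19,
                       pleiotropy_frac = 0, pleiotropy_sd = 0,
                       directional_shift = 0,
                       n_outliers = 0, outlier_magnitude = 10,
                       eaf_range = c(0.05, 0.95), z_range = c(7, 25),
                       seed) {
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) mr_error("a simulation seed is mandatory", "mr_config_error")
  stopifnot(
    pleiotropy_frac >= 0, pleiotropy_frac <= 1,
    case_fraction > 0, case_fraction < 1,
    n_exposure >= 1000, n_mediator >= 1000, n_outcome >= 1000,
    eaf_range[1] > 0, eaf_range[2] < 1, eaf_range[1] <= eaf_range[2],
    n_outliers >= 0, n_snps_exposure >= 1, n_snps_mediator >= 0
  )
  structure(list(
    n_snps_exposure = n_snps_exposure, n_snps_mediator = n_snps_mediator,
    n_exposure = n_exposure, n_mediator = n_mediator, n_outcome = n_outcome,
    outcome_type = outcome_type, case_fraction = case_fraction,
    theta_direct = theta_direct, alpha_true = alpha_true,
    beta2_true = beta2_true, pleiotropy_frac = pleiotropy_frac,
    pleiotropy_sd = pleiotropy_sd, directional_shift = directional_shift,
    n_outliers = n_outliers, outlier_magnitude = outlier_magnitude,
    eaf_range = eaf_range, z_range = z_range, seed = as.integer(seed)
  ), class = "sim_config")
}

# non-palindromic allele pairs only: strand flips are exercised through
# dedicated fixtures, while the generator keeps every planted instrument
# recoverable regardless of its allele frequency
ALLELE_PAIRS <- matrix(c(
  "A", "G", "A", "C", "G", "A", "G", "T",
  "C", "A", "C", "T", "T", "G", "T", "C"
), ncol = 2, byrow = TRUE)

se_continuous <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))
se_binary <- function(n, phi, eaf) {
  1 / sqrt(2 * n * phi * (1 - phi) * eaf * (1 - eaf))
}

#' Simulate an exposure/mediator/outcome GWAS summary-statistics triad
#'
#' Draws per-SNP allele frequencies and true instrument effects under
#' \code{\link{sim_config}}'s linear structural model, adds independent
#' per-GWAS sampling noise at the theoretical SE, and returns the three
#' summary-statistics tables together with the generating truth. SNPs are
#' placed on alternating chromosomes more than the default clumping window
#' apart, so positional clumping retains all of them; observed p-values are
#' two-sided normal.
#'
#' @param cfg a \code{sim_config}.
#' @return A \code{simulated_study}: list with \code{exposure_stats},
#'   \code{mediator_stats}, \code{outcome_stats} (each a
#'   \code{summary_stats}) and \code{truth} (theta_direct, alpha_true,
#'   beta2_true, total = theta_direct + alpha_true * beta2_true, pm_true,
#'   outlier and pleiotropic rsids).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  kx <- cfg$n_snps_exposure
  km <- cfg$n_snps_mediator
  k <- kx + km
  with_seed(cfg$seed, {
    rsid <- sprintf("rs%06d", seq_len(k))
    chrom <- as.character(rep_len(1:22, k))
    pos <- integer(k)
    for (c_ in unique(chrom)) {
      idx <- which(chrom == c_)
      pos[idx] <- 1e6 + (seq_along(idx) - 1L) * 2e7  # 20,000 kb spacing
    }
    pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), k, replace = TRUE), ,
                         drop = FALSE]
    eaf <- stats::runif(k, cfg$eaf_range[1], cfg$eaf_range[2])

    se_x <- se_continuous(cfg$n_exposure, eaf)
    se_m <- se_continuous(cfg$n_mediator, eaf)
    se_y <- if (cfg$outcome_type == "binary") {
      se_binary(cfg$n_outcome, cfg$case_fraction, eaf)
    } else {
      se_continuous(cfg$n_outcome, eaf)
    }

    z <- stats::runif(k, cfg$z_range[1], cfg$z_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    is_exp <- seq_len(k) <= kx
    gamma_true <- ifelse(is_exp, z * se_x, 0)
    delta_true <- ifelse(is_exp, 0, z * se_m)

    med_true <- cfg$alpha_true * gamma_true + delta_true

    pleio <- numeric(k)
    n_pleio <- round(cfg$pleiotropy_frac * kx)
    pleio_idx <- if (n_pleio > 0) sample(which(is_exp), n_pleio) else integer(0)
    if (n_pleio > 0) {
      pleio[pleio_idx] <- stats::rnorm(n_pleio, cfg$directional_shift,
                                       cfg$pleiotropy_sd)
    }
    out_idx <- integer(0)
    outlier_off <- numeric(k)
    if (cfg$n_outliers > 0) {
      out_idx <- sample(which(is_exp), cfg$n_outliers)
      outlier_off[out_idx] <- cfg$outlier_magnitude * se_y[out_idx] *
        sample(c(-1, 1), cfg$n_outliers, replace = TRUE)
    }
    y_true <- cfg$theta_direct * gamma_true + cfg$beta2_true * med_true +
      pleio + outlier_off

    make_stats <- function(truth, se, n, name, type) {
      beta_hat <- truth + stats::rnorm(k, 0, se)
      new_summary_stats(name, type, data.frame(
        rsid = rsid, chrom = chrom, pos = pos,
        effect_allele = pair[, 1], other_allele = pair[, 2],
        eaf = eaf, beta = beta_hat, se = se,
        pval = ztop(beta_hat / se), n = n,
        stringsAsFactors = FALSE
      ))
    }
    exposure_stats <- make_stats(gamma_true, se_x, cfg$n_exposure,
                                 "exposure", "continuous")
    mediator_stats <- make_stats(med_true, se_m, cfg$n_mediator,
                                 "mediator", "continuous")
    outcome_stats <- make_stats(y_true, se_y, cfg$n_outcome,
                                "outcome", cfg$outcome_type)

    if (!any(exposure_stats$records$pval[is_exp] < 5e-8)) {
      mr_error(paste(
        "no exposure SNP reached genome-wide significance;",
        "raise z_range or the exposure sample size"
      ), "mr_sim_scale_error")
    }
    total <- cfg$theta_direct + cfg$alpha_true * cfg$beta2_true
    structure(
      list(
        exposure_stats = exposure_stats,
        mediator_stats = mediator_stats,
        outcome_stats = outcome_stats,
        truth = list(
          theta_direct = cfg$theta_direct, alpha_true = cfg$alpha_true,
          beta2_true = cfg$beta2_true, total = total,
          pm_true = cfg$alpha_true * cfg$beta2_true / total,
          outlier_rsids = rsid[out_idx],
          pleiotropic_rsids = rsid[pleio_idx],
          gamma_true = stats::setNames(gamma_true, rsid)
        ),
        config = cfg
      ),
      class = "simulated_study"
    )
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "Simulated study: %d exposure + %d mediator SNPs; truth total = %.4g, PM = %.4f\n",
    x$config$n_snps_exposure, x$config$n_snps_mediator,
    x$truth$total, x$truth$pm_true
  ))
  invisible(x)
}

#' Machine-readable truth table for a simulated study
#'
#' @param study a \code{simulated_study}.
#' @return A one-row data frame with the generating parameters, the implied
#'   total effect and proportion mediated, and the planted outlier and
#'   pleiotropic rsids (semicolon-separated).
#' @export
truth_report <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  t <- study$truth
  data.frame(
    theta_direct = t$theta_direct, alpha_true = t$alpha_true,
    beta2_true = t$beta2_true, total = t$total, pm_true = t$pm_true,
    outlier_rsids = paste(t$outlier_rsids, collapse = ";"),
    pleiotropic_rsids = paste(t$pleiotropic_rsids, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Write a simulated study as canonical summary-statistics TSVs
#'
#' Writes \code{exposure.tsv}, \code{mediator.tsv}, \code{outcome.tsv} with
#' the canonical header (\code{rsid, chr, pos, ea, oa, eaf, beta, se, pval,
#' n}) plus \code{truth.tsv}; identical configurations (including the seed)
#' produce byte-identical files.
#'
#' @param study a \code{simulated_study}.
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  emit <- function(stats, file) {
    df <- stats$records
    names(df) <- unname(CANONICAL_HEADERS[names(df)])
    df$beta <- sprintf("%.10g", df$beta)
    df$se <- sprintf("%.10g", df$se)
    df$pval <- sprintf("%.6g", df$pval)
    df$eaf <- sprintf("%.8g", df$eaf)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  emit(study$exposure_stats, "exposure.tsv")
  emit(study$mediator_stats, "mediator.tsv")
  emit(study$outcome_stats, "outcome.tsv")
  utils::write.table(truth_report(study), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
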
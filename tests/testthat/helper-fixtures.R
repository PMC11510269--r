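# In-code fixtures shared across the suite.

# Build a harmonized set directly from effect vectors.
make_hset <- function(gamma, Gamma, se_Gamma, se_gamma = rep(0.01, length(gamma)),
                      rsid = sprintf("rs%03d", seq_along(gamma)),
                      exposure = "exposure", outcome = "outcome") {
  structure(
    list(
      exposure_name = exposure, outcome_name = outcome,
      data = data.frame(
        rsid = rsid, beta_exposure = gamma, se_exposure = se_gamma,
        beta_outcome = Gamma, se_outcome = se_Gamma,
        eaf_exposure = rep(0.3, length(gamma)), stringsAsFactors = FALSE
      ),
      dropped = data.frame(rsid = character(0), reason = character(0))
    ),
    class = "harmonized_set"
  )
}

# Build a summary_stats object from compact arguments; defaults give valid,
# well-separated biallelic SNPs.
make_stats <- function(rsid, beta, se, pval = NULL,
                       chrom = as.character(rep_len(1:22, length(rsid))),
                       pos = 1e6 + (seq_along(rsid) - 1) * 2e7,
                       ea = rep("A", length(rsid)), oa = rep("G", length(rsid)),
                       eaf = rep(0.3, length(rsid)), n = rep(1e5, length(rsid)),
                       trait_name = "trait", trait_type = "continuous") {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         records = data.frame(
           rsid = rsid, chrom = chrom, pos = pos, effect_allele = ea,
           other_allele = oa, eaf = eaf, beta = beta, se = se, pval = pval,
           n = n, stringsAsFactors = FALSE
         )),
    class = "summary_stats"
  )
}

write_stats_tsv <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# A deterministic random weighted-regression instance for oracle checks.
random_instance <- function(k, seed) {
  set.seed(seed)
  gamma <- rnorm(k, 0, 0.1)
  gamma[abs(gamma) < 0.01] <- 0.01
  list(gamma = gamma,
       Gamma = 0.3 * gamma + rnorm(k, 0, 0.02),
       se_Gamma = runif(k, 0.005, 0.05))
}

demo_study_dir <- function() {
  system.file("extdata", "demo_study", package = "mrmediate")
}
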
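# Canonical per-SNP fields expected in every summary-statistics table.
CANONICAL_FIELDS <- c(
  "rsid", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)

# Default file headers for the canonical fields (the header the generator
# writes and the reader accepts with no column map).
CANONICAL_HEADERS <- c(
  rsid = "rsid", chrom = "chr", pos = "pos", effect_allele = "ea",
  other_allele = "oa", eaf = "eaf", beta = "beta", se = "se",
  pval = "pval", n = "n"
)

VALID_BASES <- c("A", "C", "G", "T")

new_summary_stats <- function(trait_name, trait_type, records) {
  structure(
    list(trait_name = trait_name, trait_type = trait_type, records = records),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "GWAS summary statistics for '%s' (%s trait): %d SNPs\n",
    x$trait_name, x$trait_type, nrow(x$records)
  ))
  invisible(x)
}

validate_records <- function(df, label) {
  reasons <- character(0)
  drop <- rep(FALSE, nrow(df))
  flag <- function(bad, reason) {
    bad <- bad & !drop
    if (any(bad)) {
      reasons <<- c(reasons, rep(reason, sum(bad)))
      df_dropped <<- rbind(df_dropped, data.frame(
        rsid = df$rsid[bad], reason = reason, stringsAsFactors = FALSE
      ))
      drop <<- drop | bad
    }
  }
  df_dropped <- data.frame(rsid = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  num <- c("pos", "eaf", "beta", "se", "pval", "n")
  for (f in num) df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  flag(is.na(df$rsid) | !stats::complete.cases(df[num]), "missing_value")
  flag(!(df$effect_allele %in% VALID_BASES) |
         !(df$other_allele %in% VALID_BASES), "not_biallelic_snv")
  flag(df$effect_allele == df$other_allele, "identical_alleles")
  flag(df$se <= 0, "nonpositive_se")
  flag(df$eaf < 0 | df$eaf > 1, "eaf_out_of_range")
  flag(df$pval <= 0 | df$pval > 1, "pval_out_of_range")
  flag(df$n < 1, "nonpositive_n")
  flag(duplicated(df$rsid), "duplicate_rsid")
  if (nrow(df_dropped) > 0) {
    message(sprintf(
      "%s: dropped %d of %d rows at load (%s)",
      label, nrow(df_dropped), nrow(df),
      paste(sprintf("%s: %d", names(table(df_dropped$reason)),
                    table(df_dropped$reason)), collapse = ", ")
    ))
  }
  list(records = df[!drop, , drop = FALSE], dropped = df_dropped)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited per-SNP association table with a header
#' row and returns a validated \code{summary_stats} object. Rows violating
#' the per-SNP invariants (non-positive SE, allele frequency outside
#' \eqn{[0,1]}, p-value outside \eqn{(0,1]}, indels or multi-allelic records,
#' duplicated identifiers) are dropped with a logged count; the audit of
#' dropped rows is attached as the \code{"dropped"} attribute.
#'
#' @param path path to the delimited file.
#' @param trait_name name of the trait the table describes.
#' @param trait_type \code{"continuous"} (effects in SD units) or
#'   \code{"binary"} (log odds ratios).
#' @param column_map named character vector translating file headers to
#'   canonical fields: names are the canonical fields (\code{rsid},
#'   \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#'   \code{eaf}, \code{beta}, \code{se}, \code{pval}, \code{n}), values the
#'   corresponding file headers. Defaults to the canonical header
#'   (\code{rsid, chr, pos, ea, oa, eaf, beta, se, pval, n}).
#' @return A \code{summary_stats} object: list with \code{trait_name},
#'   \code{trait_type} and a \code{records} data frame in canonical fields.
#' @export
read_summary_stats <- function(path, trait_name,
                               trait_type = c("continuous", "binary"),
                               column_map = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    mr_error(sprintf("summary-statistics file not found: %s", path),
             "mr_config_error")
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  map <- CANONICAL_HEADERS
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  missing <- setdiff(CANONICAL_FIELDS, names(map))
  if (length(missing) > 0) {
    mr_error(sprintf("column map lacks canonical fields: %s",
                     paste(missing, collapse = ", ")), "mr_config_error")
  }
  absent <- map[!(map %in% names(raw))]
  if (length(absent) > 0) {
    mr_error(sprintf(
      "columns mapped for trait '%s' are absent from %s: %s",
      trait_name, path,
      paste(sprintf("%s (-> %s)", absent, names(absent)), collapse = ", ")
    ), "mr_config_error")
  }
  df <- stats::setNames(raw[, map[CANONICAL_FIELDS], drop = FALSE],
                        CANONICAL_FIELDS)
  df$rsid <- as.character(df$rsid)
  df$chrom <- as.character(df$chrom)
  v <- validate_records(df, trait_name)
  if (nrow(v$records) == 0) {
    mr_error(sprintf("no valid rows for trait '%s' in %s", trait_name, path),
             "mr_empty_input_error")
  }
  out <- new_summary_stats(trait_name, trait_type, v$records)
  attr(out, "dropped") <- v$dropped
  out
}

#' Proportion of trait variance explained by one SNP
#'
#' Computes per-SNP \eqn{R^2} as
#' \deqn{R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2 N f(1-f) SE^2}}
#' with \eqn{f} the effect-allele frequency. The frequency terms cancel
#' algebraically, so the value equals \eqn{\beta^2/(\beta^2 + N\,SE^2)}; both
#' forms are evaluated and required to agree to a relative tolerance of
#' 1e-12 as an internal consistency check.
#'
#' @param beta per-allele effect size.
#' @param eaf effect-allele frequency, strictly inside (0, 1).
#' @param se standard error of \code{beta}, positive.
#' @param n GWAS sample size.
#' @return \eqn{R^2} in \eqn{[0, 1)}; 0 when \code{beta} is 0. Vectorized.
#' @export
snp_r_squared <- function(beta, eaf, se, n) {
  if (any(eaf <= 0 | eaf >= 1)) {
    mr_error("effect-allele frequency must lie strictly inside (0, 1)",
             "mr_degenerate_allele_error")
  }
  if (any(se <= 0)) mr_error("standard errors must be positive", "mr_domain_error")
  if (any(n < 3)) mr_error("sample size must be at least 3", "mr_domain_error")
  v <- 2 * beta^2 * eaf * (1 - eaf)
  full <- v / (v + 2 * n * eaf * (1 - eaf) * se^2)
  reduced <- beta^2 / (beta^2 + n * se^2)
  stopifnot(all(abs(full - reduced) <= 1e-12 * pmax(abs(reduced), 1e-300)))
  reduced
}

#' Instrument-strength F statistic
#'
#' \eqn{F = R^2 (N - 2) / (1 - R^2)}; values above 10 are conventionally
#' taken as adequate protection against weak-instrument bias.
#'
#' @param r2 per-SNP variance explained, in (0, 1) (0 allowed, giving F = 0).
#' @param n GWAS sample size, greater than 2.
#' @return The F statistic. Vectorized.
#' @export
snp_f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) {
    mr_error("r2 must lie in [0, 1)", "mr_domain_error")
  }
  if (any(n <= 2)) mr_error("sample size must exceed 2", "mr_domain_error")
  r2 * (n - 2) / (1 - r2)
}

# Greedy clumping over a p-sorted candidate table. A candidate is kept iff
# every already-kept SNP is on another chromosome, farther than window_kb
# away, or (when the LD lookup knows the pair) in r2 below r2_max.
clump_keep <- function(df, window_kb, r2_max, ld) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    indep <- TRUE
    for (j in which(keep)) {
      if (df$chrom[i] != df$chrom[j]) next
      if (abs(df$pos[i] - df$pos[j]) / 1000 > window_kb) next
      r2_pair <- NA_real_
      if (!is.null(ld) && df$rsid[i] %in% rownames(ld) &&
            df$rsid[j] %in% colnames(ld)) {
        r2_pair <- ld[df$rsid[i], df$rsid[j]]
      }
      if (!is.na(r2_pair) && r2_pair < r2_max) next
      indep <- FALSE
      break
    }
    keep[i] <- indep
  }
  keep
}

#' Select independent, strong genetic instruments
#'
#' Greedy distance/LD clumping of genome-wide-significant SNPs followed by
#' instrument-strength screening. Candidates with association p-value below
#' \code{p_threshold} are visited in order of ascending p (ties broken by
#' rsid); a candidate is accepted iff it is independent of every
#' already-accepted SNP, where two SNPs are independent when they sit on
#' different chromosomes, or are farther apart than \code{window_kb}, or
#' (when an LD lookup is supplied) have pairwise \eqn{r^2} below
#' \code{r2_max}. Without an LD lookup, any same-chromosome pair within the
#' window is conservatively treated as correlated. Retained SNPs carry their
#' \eqn{R^2} and F statistic; instruments with \eqn{F \le} \code{f_min} are
#' removed and logged.
#'
#' @param stats a \code{summary_stats} object.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param r2_max pairwise LD threshold for independence (default 0.001).
#' @param window_kb clumping distance in kilobases (default 10000).
#' @param f_min minimum F statistic retained (default 10, strict inequality).
#' @param ld optional symmetric matrix of pairwise \eqn{r^2} with rsid
#'   dimnames; pairs absent from the matrix are treated as correlated when
#'   within the window.
#' @return An \code{instrument_set}: list with \code{trait_name},
#'   \code{trait_type} and \code{records} (canonical fields plus \code{r2}
#'   and \code{f_stat}); the audit of dropped candidates is in the
#'   \code{"dropped"} attribute (rsid, stage, reason).
#' @export
select_instruments <- function(stats, p_threshold = 5e-8, r2_max = 0.001,
                               window_kb = 10000, f_min = 10, ld = NULL) {
  stopifnot(inherits(stats, "summary_stats"))
  df <- stats$records
  dropped <- data.frame(rsid = character(0), stage = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  note <- function(rsids, stage, reason) {
    if (length(rsids) > 0) {
      dropped <<- rbind(dropped, data.frame(
        rsid = rsids, stage = stage, reason = reason, stringsAsFactors = FALSE
      ))
    }
  }
  sig <- df$pval < p_threshold
  note(df$rsid[!sig], "significance", sprintf("pval >= %g", p_threshold))
  df <- df[sig, , drop = FALSE]
  if (nrow(df) == 0) {
    mr_error(sprintf("no genome-wide-significant SNPs for trait '%s'",
                     stats$trait_name), "mr_no_instrument_error")
  }
  df <- df[order(df$pval, df$rsid), , drop = FALSE]
  keep <- clump_keep(df, window_kb, r2_max, ld)
  note(df$rsid[!keep], "clumping", "in_ld_with_retained")
  df <- df[keep, , drop = FALSE]
  df$r2 <- snp_r_squared(df$beta, df$eaf, df$se, df$n)
  df$f_stat <- snp_f_statistic(df$r2, df$n)
  weak <- df$f_stat <= f_min
  note(df$rsid[weak], "strength", sprintf("f_stat <= %g", f_min))
  if (any(weak)) {
    message(sprintf("%s: removed %d weak instrument(s) with F <= %g",
                    stats$trait_name, sum(weak), f_min))
  }
  df <- df[!weak, , drop = FALSE]
  if (nrow(df) == 0) {
    mr_error(sprintf("no instruments survive screening for trait '%s'",
                     stats$trait_name), "mr_no_instrument_error")
  }
  structure(
    list(trait_name = stats$trait_name, trait_type = stats$trait_type,
         records = df),
    class = "instrument_set", dropped = dropped
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "Instrument set for '%s': %d SNPs, F in [%.2f, %.2f]\n",
    x$trait_name, nrow(x$records),
    min(x$records$f_stat), max(x$records$f_stat)
  ))
  invisible(x)
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome associations to a common effect allele
#'
#' Aligns the outcome's per-SNP effects to the exposure's effect allele. For
#' each rsid shared by the two inputs: matching allele codes are kept as-is;
#' swapped codes flip the sign of the outcome beta (and complement its
#' allele frequency); codes matching only after strand complementation are
#' complemented and then treated the same way. Palindromic variants (A/T or
#' C/G), whose strand cannot be read off the allele codes, are oriented by
#' allele-frequency agreement and dropped as \code{"ambiguous_palindrome"}
#' when either trait's frequency lies within \code{palindrome_eaf_window} of
#' 0.5. Incompatible allele pairs are dropped with a reason.
#'
#' @param exposure an \code{instrument_set} (or \code{summary_stats}) for the
#'   exposure.
#' @param outcome a \code{summary_stats} object for the outcome.
#' @param palindrome_eaf_window half-width of the ambiguity zone around an
#'   allele frequency of 0.5 (default 0.08, i.e. drop when EAF is inside
#'   [0.42, 0.58]).
#' @return A \code{harmonized_set}: list with \code{exposure_name},
#'   \code{outcome_name}, \code{data} (rsid, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome, eaf_exposure) and \code{dropped} (rsid,
#'   reason).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, c("instrument_set", "summary_stats")),
            inherits(outcome, "summary_stats"))
  ex <- exposure$records
  out <- outcome$records
  shared <- intersect(ex$rsid, out$rsid)
  if (length(shared) == 0) {
    mr_error(sprintf(
      "no shared SNPs between '%s' instruments and '%s' summary statistics",
      exposure$trait_name, outcome$trait_name
    ), "mr_harmonization_error")
  }
  ex <- ex[match(shared, ex$rsid), , drop = FALSE]
  ou <- out[match(shared, out$rsid), , drop = FALSE]
  k <- length(shared)
  keep <- logical(k)
  reason <- character(k)
  beta_o <- ou$beta
  for (i in seq_len(k)) {
    ea_e <- ex$effect_allele[i]; oa_e <- ex$other_allele[i]
    ea_o <- ou$effect_allele[i]; oa_o <- ou$other_allele[i]
    if (is_palindromic(ea_e, oa_e)) {
      same_pair <- setequal(c(ea_o, oa_o), c(ea_e, oa_e))
      if (!same_pair) { reason[i] <- "incompatible_alleles"; next }
      if (abs(ex$eaf[i] - 0.5) <= palindrome_eaf_window ||
            abs(ou$eaf[i] - 0.5) <= palindrome_eaf_window) {
        reason[i] <- "ambiguous_palindrome"
        next
      }
      # frequency of the exposure's effect allele in the outcome, reading
      # the outcome's codes literally; strand flips are then resolved by
      # requiring the two frequencies to fall on the same side of 0.5
      f_out <- if (ea_o == ea_e) ou$eaf[i] else 1 - ou$eaf[i]
      s_letter <- if (ea_o == ea_e) 1 else -1
      s_freq <- if ((ex$eaf[i] - 0.5) * (f_out - 0.5) > 0) 1 else -1
      beta_o[i] <- ou$beta[i] * s_letter * s_freq
      keep[i] <- TRUE
    } else {
      if (ea_o == ea_e && oa_o == oa_e) {
        keep[i] <- TRUE
      } else if (ea_o == oa_e && oa_o == ea_e) {
        beta_o[i] <- -ou$beta[i]
        keep[i] <- TRUE
      } else {
        ca <- complement_allele(ea_o); co <- complement_allele(oa_o)
        if (ca == ea_e && co == oa_e) {
          keep[i] <- TRUE
        } else if (ca == oa_e && co == ea_e) {
          beta_o[i] <- -ou$beta[i]
          keep[i] <- TRUE
        } else {
          reason[i] <- "incompatible_alleles"
        }
      }
    }
  }
  data <- data.frame(
    rsid = shared[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    beta_outcome = beta_o[keep],
    se_outcome = ou$se[keep],
    eaf_exposure = ex$eaf[keep],
    stringsAsFactors = FALSE
  )
  dropped <- data.frame(rsid = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(data) == 0) {
    mr_error(sprintf(
      "harmonization of '%s' on '%s' left no usable SNPs",
      exposure$trait_name, outcome$trait_name
    ), "mr_harmonization_error")
  }
  structure(
    list(exposure_name = exposure$trait_name,
         outcome_name = outcome$trait_name,
         data = data, dropped = dropped),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf(
    "Harmonized set '%s' -> '%s': %d SNPs retained, %d dropped\n",
    x$exposure_name, x$outcome_name, nrow(x$data), nrow(x$dropped)
  ))
  invisible(x)
}

#' Write the dropped-SNP audit trail for a set of pipeline objects
#'
#' @param objects named list of objects carrying a \code{"dropped"} attribute
#'   or \code{dropped} element.
#' @param path output TSV path (columns rsid, stage, reason).
#' @return The path, invisibly.
#' @export
write_dropped_audit <- function(objects, path) {
  rows <- lapply(names(objects), function(nm) {
    o <- objects[[nm]]
    d <- attr(o, "dropped") %||% o$dropped
    if (is.null(d) || nrow(d) == 0) return(NULL)
    if (!"stage" %in% names(d)) d$stage <- nm
    data.frame(rsid = d$rsid, stage = paste(nm, d$stage, sep = ":"),
               reason = d$reason, stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, rows)
  if (is.null(audit)) {
    audit <- data.frame(rsid = character(0), stage = character(0),
                        reason = character(0))
  }
  utils::write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
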
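# Config-driven orchestration of the full workflow: instruments ->
# harmonization -> univariable MR + sensitivity battery -> two-step MR ->
# MVMR mediation, with tabular reports and a structured log.

#' Read and validate a YAML run configuration
#'
#' The configuration names the trait tables (path, trait type, optional
#' column map), lists which traits act as exposures, mediators and
#' outcomes, and sets the analysis thresholds. Relative paths are resolved
#' against the configuration file's directory. Validation happens before
#' any computation and names the offending field.
#'
#' @param path YAML file. Top-level keys: \code{traits} (named blocks with
#'   \code{file}, \code{type}, optional \code{column_map}),
#'   \code{exposures}, \code{mediators}, \code{outcomes}, \code{seed},
#'   \code{output_dir}, optional \code{settings} (any of
#'   \code{p_instrument}, \code{r2_max}, \code{window_kb}, \code{f_min},
#'   \code{palindrome_eaf_window}, \code{ivw_mode}, \code{n_boot},
#'   \code{presso_n_sim}, \code{alpha_level}) and \code{run_presso}.
#' @param overrides optional named list overriding top-level keys.
#' @return A validated \code{run_config} object.
#' @export
read_run_config <- function(path, overrides = NULL) {
  if (!file.exists(path)) {
    mr_error(sprintf("config file not found: %s", path), "mr_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(overrides)) raw[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  for (field in c("traits", "exposures", "outcomes", "seed")) {
    if (is.null(raw[[field]])) {
      mr_error(sprintf("config field '%s' is missing", field),
               "mr_config_error")
    }
  }
  raw$mediators <- raw$mediators %||% character(0)
  raw$output_dir <- raw$output_dir %||% "mr_output"
  if (!grepl("^(/|[A-Za-z]:)", raw$output_dir)) {
    raw$output_dir <- file.path(base, raw$output_dir)
  }
  for (nm in names(raw$traits)) {
    tr <- raw$traits[[nm]]
    if (is.null(tr$file)) {
      mr_error(sprintf("config field 'traits.%s.file' is missing", nm),
               "mr_config_error")
    }
    f <- tr$file
    if (!grepl("^(/|[A-Za-z]:)", f)) f <- file.path(base, f)
    if (!file.exists(f)) {
      mr_error(sprintf("config field 'traits.%s.file': no such file (%s)",
                       nm, f), "mr_config_error")
    }
    raw$traits[[nm]]$file <- f
    raw$traits[[nm]]$type <- tr$type %||% "continuous"
  }
  for (role in c("exposures", "mediators", "outcomes")) {
    unknown <- setdiff(unlist(raw[[role]]), names(raw$traits))
    if (length(unknown) > 0) {
      mr_error(sprintf("config field '%s' references undeclared trait(s): %s",
                       role, paste(unknown, collapse = ", ")),
               "mr_config_error")
    }
  }
  s <- raw$settings %||% list()
  settings <- mr_config(
    p_threshold = s$p_instrument %||% 5e-8,
    r2_max = s$r2_max %||% 0.001,
    window_kb = s$window_kb %||% 10000,
    f_min = s$f_min %||% 10,
    palindrome_eaf_window = s$palindrome_eaf_window %||% 0.08,
    ivw_mode = s$ivw_mode %||% "multiplicative_random",
    n_boot = s$n_boot %||% 1000,
    presso_n_sim = s$presso_n_sim %||% 1000,
    alpha_level = s$alpha_level %||% 0.05,
    seed = raw$seed
  )
  structure(
    list(traits = raw$traits,
         exposures = unlist(raw$exposures),
         mediators = unlist(raw$mediators),
         outcomes = unlist(raw$outcomes),
         settings = settings,
         run_presso = isTRUE(raw$run_presso %||% TRUE),
         output_dir = raw$output_dir),
    class = "run_config"
  )
}

# settings-only hash: changes iff an analytic setting, trait roster or
# input checksum changes; file paths and output locations are excluded
config_hash <- function(config) {
  input_md5 <- vapply(names(config$traits), function(nm) {
    unname(tools::md5sum(config$traits[[nm]]$file))
  }, character(1))
  analytic <- list(
    settings = config$settings,
    exposures = unname(config$exposures),
    mediators = unname(config$mediators),
    outcomes = unname(config$outcomes),
    run_presso = config$run_presso,
    inputs = as.list(input_md5)
  )
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(analytic), tmp)
  unname(tools::md5sum(tmp))
}

#' Annotate an MR results table with significance stars
#'
#' Adds a \code{stars} column using the conventional three-level legend:
#' \code{***} for p below 0.001, \code{**} below 0.01, \code{*} below 0.05
#' (strict inequalities), empty otherwise. A Bonferroni-adjusted p-value
#' column across the table's rows is appended for reference but never used
#' to filter.
#'
#' @param table data frame with a \code{pval} column.
#' @return The table with \code{stars} and \code{pval_bonferroni} appended.
#' @export
significance_flags <- function(table) {
  stopifnot("pval" %in% names(table))
  p <- table$pval
  table$stars <- ifelse(p < 0.001, "***",
                        ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  table$pval_bonferroni <- pmin(1, p * nrow(table))
  table
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full MR workflow from a configuration
#'
#' Executes, in order: instrument selection per exposure; harmonization and
#' the univariable estimator battery (IVW, MR-Egger, weighted median) with
#' the sensitivity suite (Cochran's Q, Egger intercept, optional MR-PRESSO,
#' leave-one-out) for every exposure-outcome pair; and, when mediators are
#' declared, the two-step/MVMR mediation decomposition for every
#' exposure-outcome pair with the full mediator list. A failure in one pair
#' is recorded in the skipped-pairs table and does not abort the remaining
#' pairs. All report tables are written as TSV under the configured output
#' directory along with a dropped-SNP audit, a run manifest (package
#' version, seed, configuration hash) and a plain-text log with stage
#' timings (the log is the only output carrying wall-clock times; every
#' report table is deterministic given the seed).
#'
#' @param config a \code{run_config} from \code{\link{read_run_config}}.
#' @return A \code{run_report}: list with \code{mr_table}, \code{qc_table},
#'   \code{loo_table}, \code{mediation_table}, \code{skipped},
#'   \code{manifest} and \code{output_dir}, invisibly also written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config$settings
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  t0 <- Sys.time()
  logline <- function(fmt, ...) {
    writeLines(sprintf("[%7.2fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                       sprintf(fmt, ...)), log_con)
  }
  logline("pipeline start (seed %d)", cfg$seed)

  traits <- lapply(names(config$traits), function(nm) {
    tr <- config$traits[[nm]]
    cm <- if (!is.null(tr$column_map)) unlist(tr$column_map) else NULL
    read_summary_stats(tr$file, trait_name = nm, trait_type = tr$type,
                       column_map = cm)
  })
  names(traits) <- names(config$traits)
  logline("loaded %d trait table(s)", length(traits))

  skipped <- data.frame(exposure = character(0), outcome = character(0),
                        stage = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  skip <- function(exposure, outcome, stage, e) {
    skipped <<- rbind(skipped, data.frame(
      exposure = exposure, outcome = outcome, stage = stage,
      reason = conditionMessage(e), stringsAsFactors = FALSE
    ))
    logline("SKIP %s -> %s at %s: %s", exposure, outcome, stage,
            conditionMessage(e))
  }

  instruments <- list()
  audit_objects <- list()
  for (ex in config$exposures) {
    iv <- tryCatch(select_with_config(traits[[ex]], cfg),
                   error = function(e) e)
    if (inherits(iv, "error")) {
      for (ou in config$outcomes) skip(ex, ou, "instrument_selection", iv)
    } else {
      instruments[[ex]] <- iv
      audit_objects[[paste0("instruments_", ex)]] <- iv
      logline("instruments for %s: %d SNPs, F in [%.2f, %.2f]", ex,
              nrow(iv$records), min(iv$records$f_stat), max(iv$records$f_stat))
    }
  }

  mr_rows <- list(); qc_rows <- list(); loo_rows <- list()
  pair_i <- 0L
  for (ex in intersect(config$exposures, names(instruments))) {
    for (ou in config$outcomes) {
      pair_i <- pair_i + 1L
      pair_seed <- cfg$seed + 101L * pair_i
      res <- tryCatch({
        h <- harmonize(instruments[[ex]], traits[[ou]],
                       cfg$palindrome_eaf_window)
        audit_objects[[sprintf("harmonize_%s_%s", ex, ou)]] <- h
        tab <- mr_all_methods(h, mode = cfg$ivw_mode, n_boot = cfg$n_boot,
                              seed = pair_seed)
        q <- cochran_q(h)
        eg <- if (nrow(h$data) >= 3) mr_egger(h, cfg$alpha_level) else NULL
        pr <- if (config$run_presso && nrow(h$data) >= 4) {
          mr_presso(h, n_sim = cfg$presso_n_sim, seed = pair_seed + 1L,
                    significance = cfg$alpha_level, mode = cfg$ivw_mode)
        } else NULL
        loo <- if (nrow(h$data) >= 3) leave_one_out(h, mode = cfg$ivw_mode) else NULL
        list(tab = tab, q = q, eg = eg, pr = pr, loo = loo)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skip(ex, ou, "univariable_mr", res)
        next
      }
      mr_rows[[pair_i]] <- res$tab
      qc_rows[[pair_i]] <- data.frame(
        exposure = ex, outcome = ou,
        q = res$q$q, q_pval = res$q$pval,
        egger_intercept = if (is.null(res$eg)) NA_real_ else res$eg$intercept,
        intercept_pval = if (is.null(res$eg)) NA_real_ else res$eg$intercept_pval,
        presso_global_pval = if (is.null(res$pr)) NA_real_ else res$pr$global_pval,
        n_outliers = if (is.null(res$pr)) NA_integer_ else nrow(res$pr$outliers),
        distortion_pval = if (is.null(res$pr)) NA_real_ else res$pr$distortion_pval,
        stringsAsFactors = FALSE
      )
      if (!is.null(res$loo)) {
        lt <- as.data.frame(res$loo)
        loo_rows[[pair_i]] <- cbind(exposure = ex, outcome = ou, lt)
      }
      logline("univariable MR %s -> %s done (%d SNPs)", ex, ou,
              res$tab$n_snp[1])
    }
  }

  med_rows <- list()
  if (length(config$mediators) > 0) {
    mi <- 0L
    for (ex in intersect(config$exposures, names(instruments))) {
      for (ou in config$outcomes) {
        mi <- mi + 1L
        res <- tryCatch(
          mediate(traits[[ex]], traits[config$mediators], traits[[ou]], cfg),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          skip(ex, ou, "mediation", res)
          next
        }
        med_rows[[mi]] <- as.data.frame(res)
        logline("mediation %s -> %s done", ex, ou)
      }
    }
  }

  mr_table <- if (length(mr_rows) > 0) {
    significance_flags(do.call(rbind, mr_rows))
  } else {
    data.frame()
  }
  qc_table <- do.call(rbind, qc_rows) %||% data.frame()
  loo_table <- do.call(rbind, loo_rows) %||% data.frame()
  mediation_table <- do.call(rbind, med_rows) %||% data.frame()

  pairs_run <- if (nrow(mr_table) > 0) {
    nrow(unique(mr_table[, c("exposure", "outcome")]))
  } else 0L
  mr_stage <- skipped$stage %in% c("instrument_selection", "univariable_mr")
  pairs_skipped <- if (any(mr_stage)) {
    nrow(unique(skipped[mr_stage, c("exposure", "outcome")]))
  } else 0L
  manifest <- data.frame(
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    seed = cfg$seed,
    config_hash = config_hash(config),
    n_pairs_run = pairs_run,
    n_pairs_skipped = pairs_skipped,
    stringsAsFactors = FALSE
  )
  write_tsv(mr_table, file.path(config$output_dir, "mr_results.tsv"))
  write_tsv(qc_table, file.path(config$output_dir, "qc_report.tsv"))
  write_tsv(loo_table, file.path(config$output_dir, "leave_one_out.tsv"))
  write_tsv(mediation_table, file.path(config$output_dir, "mediation.tsv"))
  write_tsv(skipped, file.path(config$output_dir, "skipped_pairs.tsv"))
  write_tsv(manifest, file.path(config$output_dir, "manifest.tsv"))
  write_dropped_audit(audit_objects,
                      file.path(config$output_dir, "dropped_snps.tsv"))
  logline("pipeline complete: %d pair(s) run, %d skipped",
          length(mr_rows), nrow(skipped))

  invisible(structure(
    list(mr_table = mr_table, qc_table = qc_table, loo_table = loo_table,
         mediation_table = mediation_table, skipped = skipped,
         manifest = manifest, output_dir = config$output_dir),
    class = "run_report"
  ))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "MR pipeline report: %d estimator row(s), %d pair(s) skipped; outputs in %s\n",
    nrow(x$mr_table), nrow(x$skipped), x$output_dir
  ))
  invisible(x)
}
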
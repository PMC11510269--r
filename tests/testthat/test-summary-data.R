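test_that("reader accepts canonical TSV and CSV and maps arbitrary headers", {
  df <- data.frame(
    rsid = c("rs1", "rs2", "rs3"), chr = "1", pos = c(1e6, 3e7, 6e7),
    ea = "A", oa = "G", eaf = 0.3, beta = c(0.1, -0.2, 0.05),
    se = 0.01, pval = c(1e-10, 1e-12, 1e-9), n = 1e5
  )
  p <- write_stats_tsv(df, tempfile(fileext = ".tsv"))
  s <- read_summary_stats(p, "t1")
  expect_s3_class(s, "summary_stats")
  expect_equal(nrow(s$records), 3)
  expect_equal(s$records$beta, df$beta)

  names(df) <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "BETA", "SE", "P", "N")
  pc <- write_stats_tsv(df, tempfile(fileext = ".csv"), sep = ",")
  s2 <- read_summary_stats(pc, "t1", column_map = c(
    rsid = "SNP", chrom = "CHR", pos = "BP", effect_allele = "A1",
    other_allele = "A2", eaf = "FRQ", beta = "BETA", se = "SE",
    pval = "P", n = "N"
  ))
  expect_equal(s2$records, s$records)
})

test_that("reader drops invalid rows with reasons and errors on bad config", {
  df <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs2", "rs6"),
    chr = "1", pos = (1:6) * 1e6, ea = c("A", "A", "ACT", "A", "A", "A"),
    oa = c("G", "G", "G", "A", "G", "G"), eaf = 0.3,
    beta = 0.1, se = c(0.01, 0, 0.01, 0.01, 0.01, 0.01),
    pval = 1e-10, n = 1e5
  )
  p <- write_stats_tsv(df, tempfile(fileext = ".tsv"))
  expect_message(s <- read_summary_stats(p, "t1"), "dropped 4 of 6")
  expect_setequal(s$records$rsid, c("rs1", "rs6"))
  audit <- attr(s, "dropped")
  expect_setequal(audit$reason[audit$rsid == "rs2"],
                  c("nonpositive_se", "duplicate_rsid"))
  expect_true("not_biallelic_snv" %in% audit$reason)
  expect_true("identical_alleles" %in% audit$reason)

  # mapped column absent from the file -> configuration error
  expect_error(
    read_summary_stats(p, "t1", column_map = c(eaf = "no_such_col")),
    class = "mr_config_error"
  )
  # all rows invalid -> empty-input error
  df_bad <- df[df$se == 0, ]
  pb <- write_stats_tsv(df_bad, tempfile(fileext = ".tsv"))
  expect_error(suppressMessages(read_summary_stats(pb, "t1")),
               class = "mr_empty_input_error")
})

test_that("per-SNP R2 matches hand-derived values and is EAF-invariant", {
  # beta = 0.1, se = 0.01, n = 1e5: R2 = 0.01/(0.01 + 10)
  expect_equal(snp_r_squared(0.1, 0.3, 0.01, 1e5), 0.01 / 10.01,
               tolerance = 1e-12)
  expect_equal(snp_r_squared(0, 0.3, 0.01, 1e5), 0)
  # the frequency terms cancel exactly
  expect_identical(snp_r_squared(0.1, 0.3, 0.01, 1e5),
                   snp_r_squared(0.1, 0.45, 0.01, 1e5))
  expect_error(snp_r_squared(0.1, 1, 0.01, 1e5),
               class = "mr_degenerate_allele_error")
})

test_that("F statistic matches hand arithmetic and is monotone", {
  expect_equal(snp_f_statistic(0.5, 4), 2)
  # plugging the reduced-form R2 from the previous example:
  # F = (0.01/10.01) * 99998 / (10/10.01) = 0.01 * 99998 / 10
  expect_equal(snp_f_statistic(0.01 / 10.01, 1e5), 99.998, tolerance = 1e-10)
  r2 <- seq(0.001, 0.01, length.out = 5)
  expect_true(all(diff(snp_f_statistic(r2, 1e4)) > 0))
  expect_true(all(snp_f_statistic(0.001, c(1e3, 1e4, 1e5)) ==
                    cummax(snp_f_statistic(0.001, c(1e3, 1e4, 1e5)))))
  expect_error(snp_f_statistic(1, 100), class = "mr_domain_error")
})

test_that("instrument selection applies distance clumping and F screening", {
  # two SNPs 5 Mb apart on chr1: only the lower-p one survives; chr2 SNP kept
  s <- make_stats(
    rsid = c("rsA", "rsB", "rsC"),
    beta = c(0.10, 0.08, 0.09), se = 0.01,
    pval = c(1e-30, 1e-20, 1e-25),
    chrom = c("1", "1", "2"), pos = c(1e6, 6e6, 1e6)
  )
  iv <- select_instruments(s)
  expect_setequal(iv$records$rsid, c("rsA", "rsC"))
  expect_true(all(iv$records$f_stat > 10))
  aud <- attr(iv, "dropped")
  expect_equal(aud$reason[aud$rsid == "rsB"], "in_ld_with_retained")

  # an LD lookup that declares the pair independent rescues rsB
  ld <- matrix(1e-4, 2, 2, dimnames = list(c("rsA", "rsB"), c("rsA", "rsB")))
  iv2 <- select_instruments(s, ld = ld)
  expect_setequal(iv2$records$rsid, c("rsA", "rsB", "rsC"))

  # weak instruments are screened out by F (a relaxed p threshold lets a
  # low-z SNP through significance; F approximately z^2 then removes it)
  sw <- make_stats(rsid = c("rs1", "rs2"), beta = c(0.1, 0.0028),
                   se = c(0.01, 0.001))
  expect_message(ivw <- select_instruments(sw, p_threshold = 0.01),
                 "weak instrument")
  expect_equal(ivw$records$rsid, "rs1")

  expect_error(select_instruments(make_stats("rs1", 0.1, 0.01, pval = 0.5)),
               class = "mr_no_instrument_error")
})

test_that("instrument selection is invariant to input row order", {
  set.seed(11)
  k <- 40
  s <- make_stats(
    rsid = sprintf("rs%02d", 1:k), beta = rnorm(k, 0, 0.1),
    se = 0.01, pval = 10^-runif(k, 8, 40),
    chrom = as.character(rep_len(1:4, k)),
    pos = rep(1e6 + (0:9) * 3e6, each = 4)
  )
  iv1 <- select_instruments(s)
  s_shuf <- s
  s_shuf$records <- s$records[sample(k), ]
  iv2 <- select_instruments(s_shuf)
  expect_equal(sort(iv1$records$rsid), sort(iv2$records$rsid))
})

test_that("harmonization aligns swapped, flipped and palindromic alleles", {
  iv <- structure(list(
    trait_name = "exp", trait_type = "continuous",
    records = make_stats(
      rsid = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
      beta = rep(0.1, 6), se = 0.01,
      ea = c("A", "A", "A", "A", "A", "C"),
      oa = c("G", "G", "G", "T", "T", "A"),
      eaf = c(0.3, 0.3, 0.3, 0.50, 0.8, 0.3)
    )$records
  ), class = "instrument_set")
  out <- make_stats(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    beta = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2), se = 0.02,
    ea = c("A", "G", "T", "A", "T", "C"),
    oa = c("G", "A", "C", "T", "A", "T"),
    eaf = c(0.3, 0.7, 0.3, 0.50, 0.2, 0.5)
  )
  h <- harmonize(iv, out)
  d <- h$data
  # rs1 identical coding: unchanged; rs2 swapped: sign flip;
  # rs3 matches after strand complementation (T/C -> A/G): unchanged
  expect_equal(d$beta_outcome[d$rsid == "rs1"], 0.2)
  expect_equal(d$beta_outcome[d$rsid == "rs2"], -0.2)
  expect_equal(d$beta_outcome[d$rsid == "rs3"], 0.2)
  # rs4 palindromic with EAF 0.50: ambiguous
  expect_equal(h$dropped$reason[h$dropped$rsid == "rs4"],
               "ambiguous_palindrome")
  # rs5 palindromic, informative EAF (0.8 vs 0.2 for swapped codes): the
  # outcome effect allele T is the exposure's other allele -> flip
  expect_equal(d$beta_outcome[d$rsid == "rs5"], -0.2)
  # rs6 allele pair C/T does not match exposure's C/A
  expect_equal(h$dropped$reason[h$dropped$rsid == "rs6"],
               "incompatible_alleles")
  # retained + dropped covers the rsid intersection exactly
  expect_setequal(c(d$rsid, h$dropped$rsid),
                  intersect(iv$records$rsid, out$records$rsid))
})

test_that("harmonizing an already-aligned pair is the identity", {
  st <- simulate_study(sim_config(n_snps_exposure = 30, n_snps_mediator = 0,
                                  seed = 5))
  iv <- select_instruments(st$exposure_stats)
  h1 <- harmonize(iv, st$outcome_stats)
  # re-express the outcome in the harmonized coding and harmonize again
  out2 <- st$outcome_stats
  idx <- match(h1$data$rsid, out2$records$rsid)
  out2$records <- out2$records[idx, ]
  out2$records$beta <- h1$data$beta_outcome
  h2 <- harmonize(iv, out2)
  expect_equal(h2$data, h1$data)
  expect_error(harmonize(iv, make_stats("zzz", 0.1, 0.01)),
               class = "mr_harmonization_error")
})
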
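# Contribution quantification and group statistics.

# minimal fit-like object for quantification unit tests
fake_fit <- function(areas, roles = NULL, total_area = 1000,
                     group = "sham", sample_id = "s1") {
  if (is.null(roles)) roles <- rep("fluorophore", length(areas))
  structure(list(
    pars = data.frame(name = names(areas), role = roles,
                      stringsAsFactors = FALSE),
    component_areas = areas, raw_integrated_area = total_area,
    group = group, sample_id = sample_id, excitation = 366
  ), class = "af_fit")
}

test_that("percent contributions split the positive modeled area", {
  f <- fake_fit(c(a = 300, b = 300))
  expect_equal(as.numeric(percent_contributions(f)), c(50, 50))

  f1 <- fake_fit(c(a = 123.4))
  expect_equal(as.numeric(percent_contributions(f1)), 100)

  # negative band excluded from the denominator, reported separately
  fn <- fake_fit(c(a = 300, b = 100, hb = -40),
                 roles = c("fluorophore", "fluorophore", "negative"))
  p <- percent_contributions(fn)
  expect_equal(as.numeric(p), c(75, 25))
  expect_equal(attr(p, "negative_area"), -40)

  fz <- fake_fit(c(a = 0, b = 0))
  expect_error(percent_contributions(fz), "not positive")
})

test_that("absolute contributions rescale percentages by the measured area", {
  expect_equal(absolute_contributions(c(x = 50), 1000), c(x = 500))
  expect_equal(absolute_contributions(c(a = 0, b = 100), 777),
               c(a = 0, b = 777))
  expect_error(absolute_contributions(c(a = 50), 0), "total_measured_area")
})

test_that("percent and absolute are mutually consistent for every record", {
  coh <- generate_cohort(default_profiles(366, groups = "sham"),
                         n_per_group = 3, seed = 12)
  tr <- coh$truth
  expect_equal(tr$absolute / tr$total_area * 100, tr$percent)
})

test_that("the arachidonic/retinol ratio reproduces the published group means", {
  expect_equal(round(aa_ret_ratio(c(retinol = 33.43,
                                    arachidonic_acid = 20.22)), 2), 0.60)
  expect_equal(round(aa_ret_ratio(c(retinol = 24.03,
                                    arachidonic_acid = 26.50)), 2), 1.10)
  expect_equal(round(aa_ret_ratio(c(retinol = 23.76,
                                    arachidonic_acid = 27.17)), 2), 1.14)
  expect_equal(aa_ret_ratio(c(retinol = 20, arachidonic_acid = 20)), 1)
  expect_error(aa_ret_ratio(c(retinol = 0, arachidonic_acid = 10)),
               "retinol")
})

test_that("scaling a spectrum leaves percents unchanged and scales absolutes", {
  pr <- default_profiles(366)$sham
  g <- generate_spectrum(pr, "s1", seed = 17)
  s1 <- normalize_spectrum(g$spectrum)
  scaled <- g$spectrum
  scaled$intensity <- scaled$intensity * 3
  s3 <- normalize_spectrum(scaled)
  f1 <- fit_af_spectrum(s1, stage = "reference", restarts = 2, seed = 1)
  f3 <- fit_af_spectrum(s3, stage = "reference", restarts = 2, seed = 1)
  p1 <- percent_contributions(f1)
  p3 <- percent_contributions(f3)
  expect_equal(as.numeric(p1), as.numeric(p3), tolerance = 1e-4)
  a1 <- absolute_contributions(p1, f1$raw_integrated_area)
  a3 <- absolute_contributions(p3, f3$raw_integrated_area)
  expect_equal(as.numeric(a3), 3 * as.numeric(a1), tolerance = 1e-4)
})

test_that("cohort-mean AA/Ret ratios track the generating compositions", {
  # pooled group means over many independent synthetic cohorts; the ratio
  # of pooled means should land on the ratio of the generating percent
  # means (0.60 / 1.10 / 1.14 for the default 366 nm profiles)
  prs <- default_profiles(366)
  sums <- NULL
  n_rep <- 300
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(prs, n_per_group = 7, seed = 50000000 + 100000 * r)
    m <- aggregate(percent ~ group + component, coh$truth, mean)
    sums <- if (is.null(sums)) m else {
      sums$percent <- sums$percent + m$percent; sums
    }
  }
  sums$percent <- sums$percent / n_rep
  ratio <- function(g) {
    p <- sums[sums$group == g, ]
    aa_ret_ratio(setNames(p$percent, p$component))
  }
  expect_equal(ratio("sham"), 0.60, tolerance = 0.05 / 0.60)
  expect_equal(ratio("ir_60_60"), 1.10, tolerance = 0.05 / 1.10)
  expect_equal(ratio("ir_60_120"), 1.14, tolerance = 0.05 / 1.14)
})

make_records <- function(vals_by_group, component = "arachidonic_acid") {
  do.call(rbind, lapply(names(vals_by_group), function(g) {
    v <- vals_by_group[[g]]
    data.frame(sample_id = paste0(g, seq_along(v)), group = g,
               excitation = 366, component = component, percent = v,
               absolute = v * 10, total_area = 1000,
               stringsAsFactors = FALSE)
  }))
}

test_that("group summaries report mean, SE and significance flags", {
  set.seed(33)
  base <- rnorm(7, 20, 1)
  rec <- make_records(list(sham = base, ir_60_60 = base,
                           ir_60_120 = base + 10 * sd(base)))
  s <- summarize_groups(rec, reference = "sham")
  expect_s3_class(s, "af_summary")
  same <- s[s$group == "ir_60_60", ]
  expect_gt(same$p_value, 0.9)
  expect_identical(same$flag, "")
  far <- s[s$group == "ir_60_120", ]
  expect_lte(far$p_value, 0.01)
  expect_identical(far$flag, "**")
  sham <- s[s$group == "sham", ]
  expect_equal(sham$se, sd(base) / sqrt(7))
  expect_true(is.na(sham$p_value))

  # rank-sum variant flags the separated group too
  sr <- summarize_groups(rec, reference = "sham", test = "ranksum")
  expect_lte(sr[sr$group == "ir_60_120", "p_value"], 0.05)
})

test_that("groups with a single sample are kept but not tested", {
  rec <- make_records(list(sham = c(19, 20, 21), tiny = 25))
  s <- summarize_groups(rec, reference = "sham")
  tiny <- s[s$group == "tiny", ]
  expect_equal(tiny$n, 1)
  expect_true(is.na(tiny$se))
  expect_true(is.na(tiny$p_value))
  expect_error(summarize_groups(rec, reference = "absent"), "reference")
})

test_that("reporting filter drops minor components but keeps boundary ones", {
  rec <- rbind(
    make_records(list(sham = c(40, 41), ir_60_60 = c(39, 40)),
                 component = "retinol"),
    make_records(list(sham = c(4.0, 4.0), ir_60_60 = c(3.9, 4.1)),
                 component = "undefined_440"),
    make_records(list(sham = c(5.0, 5.2), ir_60_60 = c(4.0, 4.2)),
                 component = "oleic_acid"))
  s <- summarize_groups(rec, reference = "sham")
  filt <- reporting_filter(s, threshold = 5)
  expect_false("undefined_440" %in% filt$component)
  expect_true("oleic_acid" %in% filt$component)   # 5.1 in one group
  expect_true("retinol" %in% filt$component)
  # raw summary unchanged
  expect_true("undefined_440" %in% s$component)
})

test_that("formatted summaries carry the published table layout", {
  rec <- rbind(
    make_records(list(sham = c(30, 34), ir_60_60 = c(20, 24)),
                 component = "retinol"),
    make_records(list(sham = c(18, 22), ir_60_60 = c(25, 29)),
                 component = "arachidonic_acid"))
  s <- summarize_groups(rec, reference = "sham")
  w <- format_summary(s)
  expect_named(w, c("group", "retinol", "arachidonic_acid", "aa_ret"))
  expect_match(w$retinol[1], "±")
  expect_equal(w$aa_ret[1], sprintf("%.2f", 20 / 32))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(s, path)
  expect_true(file.exists(path))
  expect_match(readLines(path)[1], "aa_ret")
})
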
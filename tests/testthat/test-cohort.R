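test_that("default cohort reproduces the hard count constraints for every seed", {
  spec <- default_cohort_spec()
  for (s in c(1, 7, 13, 42, seq(100, 1600, by = 100))) {
    co <- generate_cohort(spec, seed = s)
    vte <- co$status != "none"
    expect_identical(nrow(co), 526L)
    expect_identical(sum(vte), 152L)
    expect_identical(sum(co$status == "PE"), 83L)
    expect_identical(sum(co$status == "DVT"), 69L)
    expect_identical(sum(vte & co$d_dimer < 0.5), 0L)
    expect_identical(sum(vte & co$d_dimer < 1.0), 6L)
    expect_identical(sum(!vte & co$d_dimer < 0.5), 219L)
  }
})

test_that("generated records satisfy the domain invariants", {
  co <- generate_cohort(seed = 5)
  expect_true(all(co$age >= 18 & co$age <= 100))
  expect_true(all(co$d_dimer > 0))
  expect_true(all(co$status %in% c("PE", "DVT", "none")))
  expect_true(all(co$pathway[co$status == "PE"] == "CTPA"))
  expect_true(all(co$pathway[co$status == "DVT"] == "CUS"))
  expect_true(all(co$pretest %in% c("low", "moderate", "high")))
  expect_false(any(duplicated(co$patient_id)))
  # every VTE value clears the enforced zero-false-negative floors
  vte <- co[co$status != "none", ]
  for (id in c("m1", "m2", "m3")) {
    expect_true(all(vte$d_dimer >= dd_threshold(cutoff_rule(id), vte$age)))
  }
})

test_that("generation is deterministic in the seed and sensitive to it", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(generate_cohort(seed = 11), f1)
  write_cohort_csv(generate_cohort(seed = 11), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  write_cohort_csv(generate_cohort(seed = 12), f2)
  expect_false(tools::md5sum(f1) == tools::md5sum(f2))
  # the caller's RNG stream is not consumed
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_cohort(seed = 11))
  expect_identical(runif(1), before)
})

test_that("cohort CSV round trip is lossless", {
  co <- generate_cohort(seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_equal(back, co, ignore_attr = TRUE)
})

test_that("cohort CSV parsing validates content and locates bad rows", {
  co <- generate_cohort(seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)

  lines <- readLines(f)
  bad <- sub("^(P\\d+,\\d+,)[0-9.]+", "\\1-1.0", lines[4])
  writeLines(c(lines[1:3], bad, lines[5:length(lines)]), f)
  err <- tryCatch(read_cohort_csv(f), error = function(e) e)
  expect_s3_class(err, "ddcea_parse_error")
  expect_match(conditionMessage(err), "line 4")

  writeLines(lines[1], f)  # header only
  expect_identical(nrow(read_cohort_csv(f)), 0L)

  writeLines("a,b,c", f)
  expect_error(read_cohort_csv(f), class = "ddcea_parse_error")
})

test_that("infeasible constraint sets fail loudly, naming the group", {
  spec <- default_cohort_spec()
  spec$control_groups$n_below_05[2] <- 99L
  err <- tryCatch(generate_cohort(spec, seed = 1), error = function(e) e)
  expect_s3_class(err, "ddcea_constraint_infeasible")
  expect_match(conditionMessage(err), "36-45")

  # enforcing the 1.0 mg/L rule leaves no room for the sub-1.0 band
  spec2 <- default_cohort_spec()
  spec2$enforce_zero_fn_rules <- c("m1", "m4")
  expect_error(generate_cohort(spec2, seed = 1),
               class = "ddcea_constraint_infeasible")

  # removing constraints never breaks a feasible spec
  spec3 <- default_cohort_spec()
  spec3$enforce_zero_fn_rules <- character(0)
  expect_silent(co <- generate_cohort(spec3, seed = 1))
  expect_identical(nrow(co), 526L)
  spec3$vte_groups$n_below_10 <- 0L
  expect_identical(sum(generate_cohort(spec3, seed = 1)$d_dimer < 1 &
                         generate_cohort(spec3, seed = 1)$status != "none"),
                   0L)
})

test_that("group sample medians track the stratified model medians", {
  spec <- default_cohort_spec()
  n_seeds <- 200

  group_median <- function(co, g, arm) {
    sel <- co$age >= g$age_lo & co$age <= g$age_hi &
      (if (arm == "vte") co$status != "none" else co$status == "none")
    median(co$d_dimer[sel])
  }

  vte_sigma <- fit_lognormal_median_iqr(
    spec$vte_overall$median, spec$vte_overall$q25, spec$vte_overall$q75
  )$sigma
  ctl_sigma <- fit_lognormal_median_iqr(
    spec$control_overall$median, spec$control_overall$q25,
    spec$control_overall$q75
  )$sigma

  # the stratified design's implied medians stay close to the published
  # group medians for the VTE arm (deterministic check on the calibration)
  for (i in seq_len(nrow(spec$vte_groups))) {
    g <- spec$vte_groups[i, ]
    implied <- ddcea:::implied_group_median(g, vte_sigma, "vte")
    expect_lt(abs(implied - g$median) / g$median, 0.10)
  }

  cohorts <- lapply(seq_len(n_seeds), function(s) generate_cohort(spec, s))
  check_arm <- function(groups, arm, sigma) {
    for (i in seq_len(nrow(groups))) {
      g <- groups[i, ]
      if (g$n < 5) next  # singleton groups are too noisy for this summary
      implied <- ddcea:::implied_group_median(g, sigma, arm)
      obs <- median(vapply(cohorts, group_median, numeric(1), g = g,
                           arm = arm))
      expect_lt(abs(obs - implied) / implied, 0.10)
    }
  }
  check_arm(spec$vte_groups, "vte", vte_sigma)
  check_arm(spec$control_groups, "control", ctl_sigma)
})
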
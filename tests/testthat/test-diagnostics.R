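test_that("confusion tables partition the scoped cohort", {
  co <- make_cohort(
    d = c(2.0, 0.3, 5.0, 0.4, 0.8, 3.0),
    status = c("PE", "PE", "DVT", "none", "none", "none"),
    pathway = c("CTPA", "CTPA", "CUS", "CTPA", "CTPA", "CUS")
  )
  m1 <- cutoff_rule("m1")
  ct <- confusion_table(co, m1, "overall")
  expect_identical(ct$tp + ct$fn, 3L)
  expect_identical(ct$tn + ct$fp, 3L)
  expect_identical(ct$fn, 1L)   # the 0.3 PE case

  # PE scope pairs PE cases with CTPA-pathway controls only
  ct_pe <- confusion_table(co, m1, "PE")
  expect_identical(ct_pe$tp + ct_pe$fn, 2L)
  expect_identical(ct_pe$tn + ct_pe$fp, 2L)
  ct_dvt <- confusion_table(co, m1, "DVT")
  expect_identical(ct_dvt$tp + ct_dvt$fn, 1L)
  expect_identical(ct_dvt$tn + ct_dvt$fp, 1L)

  one <- make_cohort(2.0, "PE")
  ct1 <- confusion_table(one, cutoff_rule("m4"), "overall")
  expect_identical(c(ct1$tp, ct1$fp, ct1$tn, ct1$fn), c(1L, 0L, 0L, 0L))

  expect_error(confusion_table(one, m1, "DVT"), class = "ddcea_empty_scope")
})

test_that("metrics follow their defining formulas, with NA for 0/0 ratios", {
  ct <- structure(list(tp = 10, fp = 5, tn = 45, fn = 2,
                       scope = "overall", rule_id = "m4"),
                  class = "confusion_table")
  m <- metrics_from_confusion(ct)
  expect_equal(m$sensitivity, 10 / 12)
  expect_equal(m$specificity, 45 / 50)
  expect_equal(m$ppv, 10 / 15)
  expect_equal(m$npv, 45 / 47)
  expect_equal(m$plr, (10 / 12) / (1 - 45 / 50))
  expect_equal(m$nlr, (2 / 12) / (45 / 50))

  perfect <- structure(list(tp = 5, fp = 0, tn = 5, fn = 0,
                            scope = "overall", rule_id = "m1"),
                       class = "confusion_table")
  mp <- metrics_from_confusion(perfect)
  expect_equal(c(mp$sensitivity, mp$specificity, mp$ppv, mp$npv),
               rep(1, 4))
  expect_true(is.na(mp$plr))
  expect_equal(mp$nlr, 0)

  expect_error(metrics_from_confusion(structure(
    list(tp = 0, fp = 0, tn = 0, fn = 0, scope = "overall", rule_id = "m1"),
    class = "confusion_table")), class = "ddcea_degenerate_cohort")
})

test_that("predictive values are Bayes-consistent with prevalence", {
  set.seed(41)
  for (i in 1:25) {
    tp <- sample(1:50, 1); fn <- sample(0:50, 1)
    tn <- sample(1:50, 1); fp <- sample(0:50, 1)
    ct <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                         scope = "overall", rule_id = "x"),
                    class = "confusion_table")
    m <- metrics_from_confusion(ct)
    prev <- (tp + fn) / (tp + fn + tn + fp)
    bayes_ppv <- m$sensitivity * prev /
      (m$sensitivity * prev + (1 - m$specificity) * (1 - prev))
    if (!is.na(m$ppv)) expect_equal(m$ppv, bayes_ppv, tolerance = 1e-12)
  }
})

test_that("summary reconstruction reproduces published predictive values", {
  m <- metrics_from_summary(1.00, 0.65, 152, 374)
  expect_equal(m$ppv, 152 / 283, tolerance = 1e-12)
  expect_identical(format_metrics(m)$ppv_pct, 54)

  m2 <- metrics_from_summary(0.96, 0.77, 152, 374)
  expect_equal(m2$npv, 288 / 294, tolerance = 1e-12)

  m3 <- metrics_from_summary(0.5, 0.5, 10, 10)
  expect_equal(m3$plr, 1.0)

  expect_error(metrics_from_summary(1.2, 0.5, 10, 10),
               class = "ddcea_invalid_input")
})

test_that("empirical ROC is monotone with the documented endpoints", {
  roc <- empirical_roc(c(2, 1), c(TRUE, FALSE))
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))

  same <- empirical_roc(c(1, 2, 3, 1, 2, 3),
                        c(rep(TRUE, 3), rep(FALSE, 3)))
  expect_equal(roc_auc(c(1, 2, 3, 1, 2, 3),
                       c(rep(TRUE, 3), rep(FALSE, 3))), 0.5)

  set.seed(53)
  co <- random_cohort(20, 30)
  roc2 <- empirical_roc(co$d_dimer, co$status != "none")
  expect_true(all(diff(roc2$sensitivity) <= 1e-12))
  expect_true(all(diff(roc2$specificity) >= -1e-12))
  expect_identical(nrow(roc2), length(unique(co$d_dimer)) + 2L)
})

test_that("AUC equals the pairwise-comparison oracle, ties at half credit", {
  expect_equal(roc_auc(c(3, 4, 5, 1, 2, 3),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
               8.5 / 9)
  set.seed(61)
  for (i in 1:40) {
    n_case <- sample(2:30, 1)
    n_ctrl <- sample(2:30, 1)
    co <- random_cohort(n_case, n_ctrl)
    lab <- co$status != "none"
    expect_equal(roc_auc(co$d_dimer, lab),
                 brute_auc(co$d_dimer[lab], co$d_dimer[!lab]),
                 tolerance = 1e-12)
  }
})

test_that("DeLong AUC variance matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  for (i in 1:5) {
    scores <- c(rnorm(25, 1), rnorm(35))
    labels <- c(rep(TRUE, 25), rep(FALSE, 35))
    dl <- delong_ci(scores, labels)
    r <- pROC::roc(response = labels, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    expect_equal(dl$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
    expect_equal(dl$se^2, as.numeric(pROC::var(r)), tolerance = 1e-9)
    ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
    expect_equal(c(dl$lo, dl$hi), ci[c(1, 3)], tolerance = 1e-9)
  }

  sep <- delong_ci(c(10, 11, 12, 1, 2, 3),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sep$auc, 1)
  expect_equal(sep$se, 0)
  expect_error(delong_ci(c(1, 2), c(TRUE, FALSE)),
               class = "ddcea_degenerate_cohort")
})

test_that("Spearman correlation matches the tie-corrected rank definition", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1.0)
  expect_equal(spearman_rho(1:10, rev(1:10))$rho, -1.0)
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)

  set.seed(83)
  for (i in 1:10) {
    x <- sample(1:8, 30, replace = TRUE)  # heavy ties
    y <- x + sample(1:6, 30, replace = TRUE)
    mine <- spearman_rho(x, y)
    ref <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
    # invariant under strictly monotone transforms of either argument
    expect_equal(spearman_rho(exp(x), y)$rho, mine$rho)
    expect_equal(spearman_rho(x, y^3)$rho, mine$rho)
  }

  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "ddcea_undefined_correlation")
  expect_error(spearman_rho(1:3, 1:4), class = "ddcea_invalid_input")
})

test_that("evaluate_rules produces one tidy row per rule and scope", {
  co <- generate_cohort(seed = 6)
  rules <- dd_rules(co)
  m <- evaluate_rules(co, rules)
  expect_identical(nrow(m), 18L)
  expect_setequal(unique(m$scope), c("overall", "PE", "DVT"))
  # the AUC is a property of the scores, shared across rules within a scope
  for (sc in unique(m$scope)) {
    expect_identical(length(unique(m$auc[m$scope == sc])), 1L)
  }
  expect_true(all(m$auc_ci_lo <= m$auc & m$auc <= m$auc_ci_hi))
  empty <- evaluate_rules(co, list())
  expect_identical(nrow(empty), 0L)
  expect_true("rule_id" %in% names(empty))
})
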
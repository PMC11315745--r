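# Diagnostic performance: confusion tables, predictive values, likelihood
# ratios, empirical ROC, AUC with DeLong variance, Spearman correlation.

scope_selector <- function(cohort, scope) {
  switch(scope,
    overall = rep(TRUE, nrow(cohort)),
    # The source study never states which controls enter the PE vs DVT
    # analyses; scoped analyses here pair cases with the controls on the
    # same imaging pathway (CTPA for PE, CUS for DVT).
    PE = cohort$status == "PE" |
      (cohort$status == "none" & cohort$pathway == "CTPA"),
    DVT = cohort$status == "DVT" |
      (cohort$status == "none" & cohort$pathway == "CUS")
  )
}

#' Confusion table for a rule on a (possibly scoped) cohort
#'
#' Positive calls (imaging required) on cases are true positives; negative
#' calls on cases are the false negatives that make a rule-out strategy
#' unsafe.
#'
#' @param cohort A cohort tibble.
#' @param rule A `cutoff_rule`.
#' @param scope `"overall"`, `"PE"` (PE cases vs CTPA-pathway controls), or
#'   `"DVT"` (DVT cases vs CUS-pathway controls).
#' @return A `confusion_table` with fields `tp`, `fp`, `tn`, `fn`,
#'   `scope`, `rule_id`.
#' @export
confusion_table <- function(cohort, rule, scope = c("overall", "PE", "DVT")) {
  scope <- match.arg(scope)
  sub <- cohort[scope_selector(cohort, scope), ]
  if (nrow(sub) == 0) {
    dd_error(sprintf("no patients in scope %s", scope), "ddcea_empty_scope")
  }
  case <- sub$status != "none"
  pos <- dd_classify(sub, rule)$call == "positive"
  structure(
    list(tp = sum(case & pos), fp = sum(!case & pos),
         tn = sum(!case & !pos), fn = sum(case & !pos),
         scope = scope, rule_id = rule$rule_id),
    class = "confusion_table"
  )
}

#' Likelihood ratios from a sensitivity/specificity pair
#'
#' PLR = sens / (1 - spec), NLR = (1 - sens) / spec, computed directly from
#' the supplied (possibly published) proportions.  Ratios whose denominator
#' is zero are reported as `NA` (the table dash).
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return List with `plr` and `nlr`.
#' @examples
#' likelihood_ratios(0.64, 0.95)$plr  # 12.8
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  list(
    plr = if (specificity >= 1) NA_real_ else sensitivity / (1 - specificity),
    nlr = if (specificity <= 0) NA_real_ else (1 - sensitivity) / specificity
  )
}

#' Diagnostic metrics from a confusion table
#'
#' @param ct A `confusion_table`.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`, `plr`,
#'   `nlr`, `n_false_neg`.  Undefined ratios (zero denominators) are `NA`.
#' @export
metrics_from_confusion <- function(ct) {
  n_pos <- ct$tp + ct$fn
  n_neg <- ct$tn + ct$fp
  if (n_pos == 0 || n_neg == 0) {
    dd_error("confusion table needs at least one case and one control",
             "ddcea_degenerate_cohort")
  }
  sens <- ct$tp / n_pos
  spec <- ct$tn / n_neg
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  lr <- likelihood_ratios(sens, spec)
  list(
    sensitivity = sens, specificity = spec,
    ppv = ratio(ct$tp, ct$tp + ct$fp),
    npv = ratio(ct$tn, ct$tn + ct$fn),
    plr = lr$plr, nlr = lr$nlr,
    n_false_neg = ct$fn
  )
}

#' Reconstruct metrics from published summary figures
#'
#' Rebuilds the 2x2 counts from printed sensitivity/specificity and the
#' case/control totals (`tp = round(sens * n_pos)` etc., half-up), from
#' which predictive values follow.  Likelihood ratios are computed directly
#' from the quoted proportions rather than the rounded count
#' reconstruction, which is how the published ratios were derived.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @param n_pos,n_neg Case and control totals.
#' @return As [metrics_from_confusion()].
#' @examples
#' m <- metrics_from_summary(1.00, 0.65, 152, 374)
#' format_metrics(m)$ppv_pct  # 54
#' @export
metrics_from_summary <- function(sensitivity, specificity, n_pos, n_neg) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 ||
      specificity > 1 || n_pos <= 0 || n_neg <= 0) {
    dd_error("summary inputs out of range", "ddcea_invalid_input")
  }
  tp <- round_half_up(sensitivity * n_pos)
  tn <- round_half_up(specificity * n_neg)
  ct <- structure(
    list(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp,
         scope = "overall", rule_id = NA_character_),
    class = "confusion_table"
  )
  m <- metrics_from_confusion(ct)
  lr <- likelihood_ratios(sensitivity, specificity)
  m$sensitivity <- sensitivity
  m$specificity <- specificity
  m$plr <- lr$plr
  m$nlr <- lr$nlr
  m
}

#' Display-round a metrics list
#'
#' Half-up rounding to the conventional display precision: integer
#' percentages, one-decimal likelihood ratios.  Internal computations are
#' never rounded; this is a formatting layer only.
#'
#' @param m A metrics list.
#' @return List of display values.
#' @export
format_metrics <- function(m) {
  list(
    sensitivity_pct = round_half_up(100 * m$sensitivity),
    specificity_pct = round_half_up(100 * m$specificity),
    ppv_pct = round_half_up(100 * m$ppv),
    npv_pct = round_half_up(100 * m$npv),
    plr = round_half_up(m$plr, 1),
    nlr = round_half_up(m$nlr, 1),
    n_false_neg = m$n_false_neg
  )
}

check_two_class <- function(labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    dd_error("need at least one case and one control", "ddcea_degenerate_cohort")
  }
  labels
}

#' Empirical ROC curve
#'
#' One point per distinct observed score plus the two trivial endpoints,
#' under the convention that scores strictly below the threshold are
#' negative.  Sensitivity is non-increasing and specificity non-decreasing
#' as the threshold rises.
#'
#' @param scores Numeric scores (here, D-dimer in mg/L); higher indicates
#'   disease.
#' @param labels Case indicator (`TRUE` = case).
#' @return Tibble with `threshold`, `sensitivity`, `specificity`.
#' @export
empirical_roc <- function(scores, labels) {
  labels <- check_two_class(labels)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  tibble::tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[labels] >= t),
                         numeric(1)),
    specificity = vapply(thr, function(t) mean(scores[!labels] < t),
                         numeric(1))
  )
}

#' Nonparametric AUC (Mann-Whitney, ties get half credit)
#'
#' @inheritParams empirical_roc
#' @return AUC in `[0, 1]`, equal to the probability that a random case
#'   scores above a random control (ties counted 1/2).
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_two_class(labels)
  m <- sum(labels)
  n <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

#' AUC with DeLong variance and confidence interval
#'
#' The nonparametric AUC variance of DeLong, DeLong and Clarke-Pearson:
#' placement values of each case against the control sample (V10) and of
#' each control against the case sample (V01) give
#' `var(AUC) = var(V10)/m + var(V01)/n`; the Wald interval is clipped to
#' `[0, 1]`.
#'
#' @inheritParams empirical_roc
#' @param level Confidence level, default 0.95.
#' @return List with `auc`, `se`, `lo`, `hi`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- check_two_class(labels)
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x)
  n <- length(y)
  if (m < 2 || n < 2) {
    dd_error("DeLong variance needs at least two cases and two controls",
             "ddcea_degenerate_cohort")
  }
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  se <- sqrt(var(rowMeans(psi)) / m + var(colMeans(psi)) / n)
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc, se = se,
       lo = max(0, auc - z * se), hi = min(1, auc + z * se))
}

#' Spearman rank correlation with tie correction
#'
#' Pearson correlation of mid-ranks (the tie-corrected definition), with a
#' two-sided p-value from the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return List with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    dd_error("need equal-length vectors with at least 3 observations",
             "ddcea_invalid_input")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    dd_error("correlation is undefined for a constant vector",
             "ddcea_undefined_correlation")
  }
  rho <- cor(rx, ry)
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p_value = 2 * pt(-abs(tstat), n - 2))
}

#' Evaluate a rule set across scopes
#'
#' Tidy performance table mirroring the study's per-strategy layout: one
#' row per rule and scope with sensitivity, specificity, predictive
#' values, likelihood ratios, the scope's AUC with DeLong CI (shared by
#' all rules, since every strategy thresholds the same score), and the
#' false-negative count.
#'
#' @param cohort A cohort tibble.
#' @param rules Named list of `cutoff_rule` objects (see [dd_rules()]).
#' @param scopes Subset of `c("overall", "PE", "DVT")`.
#' @param ci_level Confidence level for the AUC interval.
#' @return A tibble.
#' @export
evaluate_rules <- function(cohort, rules, scopes = c("overall", "PE", "DVT"),
                           ci_level = 0.95) {
  empty <- tibble::tibble(
    rule_id = character(), scope = character(), threshold = numeric(),
    sensitivity = numeric(), specificity = numeric(), ppv = numeric(),
    npv = numeric(), plr = numeric(), nlr = numeric(), auc = numeric(),
    auc_ci_lo = numeric(), auc_ci_hi = numeric(), n_false_neg = integer()
  )
  if (!length(rules)) return(empty)
  rows <- list()
  for (scope in scopes) {
    sub <- cohort[scope_selector(cohort, scope), ]
    au <- delong_ci(sub$d_dimer, sub$status != "none", ci_level)
    for (rule in rules) {
      m <- metrics_from_confusion(confusion_table(cohort, rule, scope))
      rows[[length(rows) + 1]] <- tibble::tibble(
        rule_id = rule$rule_id, scope = scope,
        threshold = rule$fixed_value %||% NA_real_,
        sensitivity = m$sensitivity, specificity = m$specificity,
        ppv = m$ppv, npv = m$npv, plr = m$plr, nlr = m$nlr,
        auc = au$auc, auc_ci_lo = au$lo, auc_ci_hi = au$hi,
        n_false_neg = as.integer(m$n_false_neg)
      )
    }
  }
  do.call(rbind, rows)
}
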
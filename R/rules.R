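# The six D-dimer rule-out strategies as threshold functions of age.

RULE_INFO <- data.frame(
  rule_id = c("m1", "m2", "m3", "m4", "m5", "m6"),
  name = c(
    "Rule-out cut-off [0.5 mg/L]",
    "Age-adjusted cut-off [age x 0.01 mg/L]",
    "Inverse age-adjusted cut-off [0.5 + (66 - age) x 0.01 mg/L]",
    "Increased fixed cut-off [1 mg/L]",
    "95%-specificity cut-off",
    "ROC-optimal cut-off"
  ),
  kind = c("fixed", "age_adjusted", "inverse_age_adjusted", "fixed",
           "data_derived", "data_derived"),
  stringsAsFactors = FALSE
)

#' Construct a D-dimer cut-off rule
#'
#' The six strategies, addressable by id:
#'
#' * `m1` - conventional fixed rule-out cut-off, 0.5 mg/L;
#' * `m2` - age-adjusted: 0.5 mg/L up to age 50, then age x 0.01 mg/L
#'   (the classic "age x 10 ug/L" rule in mg/L units);
#' * `m3` - inverse age-adjusted: 0.5 + (66 - age) x 0.01 mg/L below age
#'   66, clamped at 0.5 mg/L from 66 on (a rule-out threshold below the
#'   assay's 0.5 mg/L convention would be meaningless);
#' * `m4` - increased fixed cut-off, 1.0 mg/L;
#' * `m5` - data-derived cut-off achieving a target specificity (95% by
#'   default), see [resolve_specificity_cutoff()];
#' * `m6` - data-derived ROC-optimal (Youden) cut-off, see
#'   [resolve_roc_optimal_cutoff()].
#'
#' Data-derived rules are unusable until `fixed_value` is set, either
#' directly (e.g. to the published 4.9 / 9.9 mg/L) or by resolving against
#' a cohort with [dd_rules()].
#'
#' @param rule_id One of `"m1"` ... `"m6"` (case-insensitive).
#' @param fixed_value Threshold in mg/L for fixed or resolved data-derived
#'   rules; defaults to 0.5 for `m1` and 1.0 for `m4`.
#' @return A `cutoff_rule` object.
#' @export
cutoff_rule <- function(rule_id, fixed_value = NULL) {
  rule_id <- tolower(rule_id)
  if (!rule_id %in% RULE_INFO$rule_id) {
    dd_error(paste0("unknown rule id: ", rule_id), "ddcea_config_error")
  }
  info <- RULE_INFO[RULE_INFO$rule_id == rule_id, ]
  if (info$kind == "fixed" && is.null(fixed_value)) {
    fixed_value <- if (rule_id == "m1") 0.5 else 1.0
  }
  if (!is.null(fixed_value) && fixed_value <= 0) {
    dd_error("fixed_value must be positive", "ddcea_config_error")
  }
  structure(
    list(rule_id = rule_id, name = info$name, kind = info$kind,
         fixed_value = fixed_value),
    class = "cutoff_rule"
  )
}

#' @export
print.cutoff_rule <- function(x, ...) {
  thr <- if (is.null(x$fixed_value)) "unresolved" else
    sprintf("%.3f mg/L", x$fixed_value)
  cat(sprintf("<cutoff_rule %s> %s (%s, %s)\n", x$rule_id, x$name, x$kind,
              thr))
  invisible(x)
}

#' Rule-out threshold for a patient of a given age
#'
#' @param rule A `cutoff_rule`.
#' @param age Integer age(s) in years, at least 18.
#' @return Threshold(s) in mg/L.  Never below 0.5 mg/L for the
#'   age-dependent rules.
#' @examples
#' dd_threshold(cutoff_rule("m2"), c(40, 75))  # 0.50, 0.75
#' @export
dd_threshold <- function(rule, age) {
  if (any(age < 18)) {
    dd_error("rules are defined for adults (age >= 18)", "ddcea_invalid_input")
  }
  switch(rule$kind,
    fixed = rep(rule$fixed_value, length(age)),
    age_adjusted = ifelse(age > 50, age * 0.01, 0.5),
    inverse_age_adjusted = pmax(ifelse(age < 66, 0.5 + (66 - age) * 0.01, 0.5),
                                0.5),
    data_derived = {
      if (is.null(rule$fixed_value)) {
        dd_error(
          sprintf("rule %s is data-derived and has not been resolved against a cohort",
                  rule$rule_id),
          "ddcea_unresolved_rule"
        )
      }
      rep(rule$fixed_value, length(age))
    }
  )
}

#' Classify a cohort under a cut-off rule
#'
#' A patient is negative (VTE excluded, imaging avoided) iff their D-dimer
#' is strictly below their threshold; a value exactly at the threshold is
#' positive (imaging required).
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param rule A `cutoff_rule`.
#' @return Tibble with columns `patient_id`, `rule_id`, `threshold`,
#'   `call` (`"negative"` / `"positive"`).
#' @export
dd_classify <- function(cohort, rule) {
  thr <- dd_threshold(rule, cohort$age)
  tibble::tibble(
    patient_id = cohort$patient_id,
    rule_id = rule$rule_id,
    threshold = thr,
    call = ifelse(cohort$d_dimer < thr, "negative", "positive")
  )
}

#' Resolve the cut-off achieving a target specificity
#'
#' Returns the smallest observed D-dimer value `t` in the cohort such that
#' the fraction of controls strictly below `t` is at least the target, so
#' the specificity of the resulting rule is guaranteed to meet the target.
#' Candidate thresholds are the observed values plus `Inf` (the empirical
#' convention: between observed values specificity is constant, so nothing
#' is gained off-grid).
#'
#' @param cohort A cohort tibble with at least one control.
#' @param target_specificity Target specificity in (0, 1].
#' @return Threshold in mg/L (possibly `Inf` if no finite observed value
#'   reaches the target).
#' @export
resolve_specificity_cutoff <- function(cohort, target_specificity = 0.95) {
  if (target_specificity <= 0 || target_specificity > 1) {
    dd_error("target_specificity must lie in (0, 1]", "ddcea_invalid_input")
  }
  ctrl <- cohort$d_dimer[cohort$status == "none"]
  if (!length(ctrl)) {
    dd_error("cohort contains no control patients", "ddcea_no_controls")
  }
  cand <- c(sort(unique(cohort$d_dimer)), Inf)
  spec_at <- vapply(cand, function(t) mean(ctrl < t), numeric(1))
  cand[which(spec_at >= target_specificity)[1]]
}

#' Resolve the ROC-optimal (Youden) cut-off
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the observed
#' values (plus `Inf`), under the classification convention of
#' [dd_classify()].  Ties are broken toward the lower threshold.
#'
#' @param cohort A cohort tibble with at least one case and one control.
#' @return Threshold in mg/L.
#' @export
resolve_roc_optimal_cutoff <- function(cohort) {
  cases <- cohort$d_dimer[cohort$status != "none"]
  ctrl <- cohort$d_dimer[cohort$status == "none"]
  if (!length(cases) || !length(ctrl)) {
    dd_error("need at least one case and one control", "ddcea_degenerate_cohort")
  }
  cand <- c(sort(unique(cohort$d_dimer)), Inf)
  j <- vapply(cand, function(t) mean(cases >= t) + mean(ctrl < t) - 1,
              numeric(1))
  cand[which.max(j)]
}

#' Build (and optionally resolve) a set of cut-off rules
#'
#' @param cohort Optional cohort used to resolve the data-derived rules
#'   (`m5`, `m6`); if `NULL` those rules stay unresolved.
#' @param ids Rule ids to include.
#' @param target_specificity Target for `m5`.
#' @return Named list of `cutoff_rule` objects.
#' @export
dd_rules <- function(cohort = NULL, ids = RULE_INFO$rule_id,
                     target_specificity = 0.95) {
  rules <- lapply(ids, cutoff_rule)
  names(rules) <- tolower(ids)
  if (!is.null(cohort)) {
    for (id in names(rules)) {
      if (rules[[id]]$kind == "data_derived") {
        rules[[id]]$fixed_value <- if (id == "m5") {
          resolve_specificity_cutoff(cohort, target_specificity)
        } else {
          resolve_roc_optimal_cutoff(cohort)
        }
      }
    }
  }
  rules
}
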
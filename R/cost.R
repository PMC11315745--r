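# Cost-minimization: imaging examinations avoided relative to the 0.5 mg/L
# reference strategy, priced under EUR (German medical fee schedule) and USD
# schedules, extrapolated to an annual volume.
#
# D-dimer testing costs cancel between strategies (every strategy tests
# every non-high-pretest patient) and therefore never enter savings; they
# enter only the optional percent-reduction baseline.

#' Price schedule for the diagnostic work-up
#'
#' @param currency ISO currency code.
#' @param price_cus,price_ddimer,price_ctpa Positive prices per
#'   examination.
#' @return A `price_schedule` object.
#' @export
price_schedule <- function(currency, price_cus, price_ddimer, price_ctpa) {
  if (any(c(price_cus, price_ddimer, price_ctpa) <= 0)) {
    dd_error("prices must be positive", "ddcea_config_error")
  }
  structure(
    list(currency = currency, price_cus = price_cus,
         price_ddimer = price_ddimer, price_ctpa = price_ctpa),
    class = "price_schedule"
  )
}

#' @rdname price_schedule
#' @param path Path to a YAML file with keys `currency`, `price_cus`,
#'   `price_ddimer`, `price_ctpa`.
#' @export
read_price_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  price_schedule(raw$currency, raw$price_cus, raw$price_ddimer,
                 raw$price_ctpa)
}

#' @rdname price_schedule
#' @details `default_price_schedules()` returns the two shipped schedules:
#'   the German medical fee schedule (CUS EUR 18.89, D-dimer EUR 24.13,
#'   CTPA EUR 209.83) and published US statutory-insurance averages
#'   (CUS $184, D-dimer $14, CTPA $648).
#' @export
default_price_schedules <- function() {
  list(
    EUR = read_price_schedule(system.file("extdata", "prices_eur.yaml",
                                          package = "ddcea", mustWork = TRUE)),
    USD = read_price_schedule(system.file("extdata", "prices_usd.yaml",
                                          package = "ddcea", mustWork = TRUE))
  )
}

#' Annual case volume for extrapolation
#'
#' Defaults to the study department's assumption of 5475 patients with
#' cancer and suspected VTE per year (1825 suspected PE, 3650 suspected
#' DVT; about 5 and 10 patients per day).
#'
#' @param total,pe,dvt Counts with `pe + dvt == total`.
#' @return List with `total`, `pe`, `dvt`.
#' @export
annual_volume <- function(total = 5475, pe = 1825, dvt = 3650) {
  if (pe + dvt != total) {
    dd_error("pe + dvt must equal total", "ddcea_config_error")
  }
  list(total = total, pe = pe, dvt = dvt)
}

#' Count imaging examinations saved by a strategy
#'
#' Imaging is performed only when the D-dimer exceeds the strategy's
#' cut-off, so a patient's examination is saved iff the reference rule
#' calls them positive while the evaluated rule calls them negative.
#' Counts are split by imaging pathway (CTPA vs CUS).
#'
#' @param cohort A cohort tibble.
#' @param rule,reference `cutoff_rule` objects (resolved).
#' @return A `saved_exams` list: `rule_id`, `n_ctpa_saved`, `n_cus_saved`.
#' @export
count_saved_exams <- function(cohort, rule, reference) {
  neg_rule <- dd_classify(cohort, rule)$call == "negative"
  pos_ref <- dd_classify(cohort, reference)$call == "positive"
  saved <- pos_ref & neg_rule
  saved_exams(rule$rule_id,
              sum(saved & cohort$pathway == "CTPA"),
              sum(saved & cohort$pathway == "CUS"))
}

#' Saved-examination counts
#'
#' Constructor used both for computed counts ([count_saved_exams()]) and
#' for feeding published counts through the price schedules.
#'
#' @param rule_id Rule id the counts belong to.
#' @param n_ctpa_saved,n_cus_saved Non-negative counts.
#' @return A `saved_exams` list.
#' @export
saved_exams <- function(rule_id, n_ctpa_saved, n_cus_saved) {
  if (n_ctpa_saved < 0 || n_cus_saved < 0) {
    dd_error("saved-examination counts must be non-negative",
             "ddcea_invalid_input")
  }
  structure(
    list(rule_id = rule_id, n_ctpa_saved = n_ctpa_saved,
         n_cus_saved = n_cus_saved),
    class = "saved_exams"
  )
}

#' Price saved examinations under a schedule
#'
#' Component and total savings are kept unrounded internally; display
#' values are rounded half-up to whole currency units.  Downstream
#' annualization always uses the unrounded total (rounding first would
#' change the annual figures).
#'
#' @param saved A `saved_exams` object.
#' @param prices A `price_schedule`.
#' @return A `savings_report` list with unrounded `savings_ctpa`,
#'   `savings_cus`, `savings_total` and `_display` counterparts.
#' @examples
#' eur <- price_schedule("EUR", 18.89, 24.13, 209.83)
#' savings_from_counts(saved_exams("m2", 43, 18), eur)$savings_total_display
#' @export
savings_from_counts <- function(saved, prices) {
  s_ctpa <- saved$n_ctpa_saved * prices$price_ctpa
  s_cus <- saved$n_cus_saved * prices$price_cus
  structure(
    list(
      rule_id = saved$rule_id, currency = prices$currency,
      n_ctpa_saved = saved$n_ctpa_saved, n_cus_saved = saved$n_cus_saved,
      savings_ctpa = s_ctpa, savings_cus = s_cus,
      savings_total = s_ctpa + s_cus,
      savings_ctpa_display = round_half_up(s_ctpa),
      savings_cus_display = round_half_up(s_cus),
      savings_total_display = round_half_up(s_ctpa + s_cus)
    ),
    class = "savings_report"
  )
}

#' Extrapolate cohort savings to an annual volume
#'
#' Scales the unrounded cohort total by `annual$total / cohort_n` and
#' display-rounds the result to whole currency units.
#'
#' @param report A `savings_report`.
#' @param cohort_n Size of the cohort the savings were measured on.
#' @param annual An [annual_volume()].
#' @return Annualized savings, rounded to whole currency units.
#' @export
annualize <- function(report, cohort_n = 526, annual = annual_volume()) {
  if (cohort_n <= 0) {
    dd_error("cohort_n must be positive", "ddcea_invalid_input")
  }
  round_half_up(report$savings_total * annual$total / cohort_n)
}

#' Percent cost reduction relative to a baseline
#'
#' @param savings Monetary savings.
#' @param baseline Positive baseline cost; see
#'   [reference_pathway_cost()] for the default baseline definition.
#' @return `100 * savings / baseline`.
#' @export
percent_reduction <- function(savings, baseline) {
  if (baseline <= 0) {
    dd_error("baseline must be positive", "ddcea_invalid_input")
  }
  100 * savings / baseline
}

#' Diagnostic cost of a pathway subgroup under the reference strategy
#'
#' Default percent-reduction baseline: within one imaging pathway, every
#' patient receives a D-dimer test and imaging is performed for every
#' reference-positive patient.  The published reduction percentages never
#' state their denominator, so this definition is explicit and
#' configurable rather than an attempted reconstruction.
#'
#' @param cohort A cohort tibble.
#' @param reference A resolved `cutoff_rule`.
#' @param prices A `price_schedule`.
#' @param pathway `"CTPA"` or `"CUS"`.
#' @return Total cost in the schedule's currency.
#' @export
reference_pathway_cost <- function(cohort, reference, prices,
                                   pathway = c("CTPA", "CUS")) {
  pathway <- match.arg(pathway)
  sub <- cohort[cohort$pathway == pathway, ]
  if (nrow(sub) == 0) {
    dd_error(sprintf("no patients on pathway %s", pathway), "ddcea_empty_scope")
  }
  n_imaging <- sum(dd_classify(sub, reference)$call == "positive")
  price_img <- if (pathway == "CTPA") prices$price_ctpa else prices$price_cus
  n_imaging * price_img + nrow(sub) * prices$price_ddimer
}

#' Savings table across rules and currencies
#'
#' @param cohort A cohort tibble.
#' @param rules Named list of resolved `cutoff_rule`s to evaluate.
#' @param reference The reference `cutoff_rule`.
#' @param prices List of `price_schedule`s.
#' @param cohort_n Cohort size for annualization (defaults to the cohort).
#' @param annual An [annual_volume()].
#' @return Tidy tibble, one row per rule x currency, with saved-exam
#'   counts, display-rounded component/total savings, and annualized
#'   savings.
#' @export
savings_table <- function(cohort, rules, reference,
                          prices = default_price_schedules(),
                          cohort_n = nrow(cohort), annual = annual_volume()) {
  rows <- lapply(rules, function(rule) {
    saved <- count_saved_exams(cohort, rule, reference)
    do.call(rbind, lapply(prices, function(p) {
      rep <- savings_from_counts(saved, p)
      tibble::tibble(
        rule_id = rep$rule_id, currency = rep$currency,
        n_ctpa_saved = rep$n_ctpa_saved, n_cus_saved = rep$n_cus_saved,
        savings_ctpa = rep$savings_ctpa_display,
        savings_cus = rep$savings_cus_display,
        savings_total = rep$savings_total_display,
        annualized = annualize(rep, cohort_n, annual)
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
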
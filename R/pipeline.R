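# Orchestration: simulate -> classify -> evaluate -> cost -> report, driven
# by a validated configuration, with seeded byte-reproducible outputs.

#' Build a run configuration
#'
#' Validates eagerly so misconfigurations fail before any computation.
#' Exactly one cohort source is used: a cohort CSV (takes precedence) or a
#' cohort specification (path, `cohort_spec` object, or `NULL` for the
#' shipped default).
#'
#' @param cohort_spec Path to a YAML spec, a `cohort_spec`, or `NULL`.
#' @param cohort_csv Optional path to an existing cohort CSV.
#' @param rules Rule ids to evaluate.
#' @param reference Reference rule id (must be among `rules`).
#' @param cost_rules Rule ids entering the cost analysis.  The ROC-optimal
#'   rule (`m6`) is excluded by default because its false-negative count
#'   makes it unsafe as a rule-out strategy; include it explicitly to
#'   override.
#' @param price_files Optional character vector of price-schedule YAML
#'   paths; `NULL` uses the shipped EUR and USD schedules.
#' @param annual An [annual_volume()].
#' @param cohort_n Cohort size used for annualization.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the synthetic stage.
#' @param target_specificity Target for resolving `m5`.
#' @param verbose Emit one log line per stage.
#' @return A `run_config` object.
#' @export
run_config <- function(cohort_spec = NULL, cohort_csv = NULL,
                       rules = c("m1", "m2", "m3", "m4", "m5", "m6"),
                       reference = "m1",
                       cost_rules = c("m2", "m3", "m4", "m5"),
                       price_files = NULL, annual = annual_volume(),
                       cohort_n = 526, out_dir = tempfile("ddcea-run-"),
                       seed = 1L, target_specificity = 0.95,
                       verbose = TRUE) {
  rules <- tolower(rules)
  reference <- tolower(reference)
  cost_rules <- tolower(cost_rules)
  bad <- setdiff(c(rules, reference, cost_rules), RULE_INFO$rule_id)
  if (length(bad)) {
    dd_error(paste0("unknown rule id(s): ", paste(unique(bad), collapse = ", ")),
             "ddcea_config_error")
  }
  if (!reference %in% rules) {
    dd_error("reference rule must be among the evaluated rules",
             "ddcea_config_error")
  }
  if (!all(cost_rules %in% rules)) {
    dd_error("cost rules must be among the evaluated rules",
             "ddcea_config_error")
  }
  if (!is.null(cohort_csv) && !file.exists(cohort_csv)) {
    dd_error(paste0("cohort CSV not found: ", cohort_csv), "ddcea_config_error")
  }
  if (is.character(cohort_spec) && !file.exists(cohort_spec)) {
    dd_error(paste0("cohort spec not found: ", cohort_spec),
             "ddcea_config_error")
  }
  structure(
    list(cohort_spec = cohort_spec, cohort_csv = cohort_csv, rules = rules,
         reference = reference, cost_rules = cost_rules,
         price_files = price_files, annual = annual, cohort_n = cohort_n,
         out_dir = out_dir, seed = as.integer(seed),
         target_specificity = target_specificity, verbose = verbose),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_config()]; `annual` may be
#' a mapping with `total`/`pe`/`dvt`.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  annual <- if (is.null(raw$annual)) annual_volume() else {
    annual_volume(raw$annual$total %||% 5475, raw$annual$pe %||% 1825,
                  raw$annual$dvt %||% 3650)
  }
  run_config(
    cohort_spec = raw$cohort_spec, cohort_csv = raw$cohort_csv,
    rules = raw$rules %||% c("m1", "m2", "m3", "m4", "m5", "m6"),
    reference = raw$reference %||% "m1",
    cost_rules = raw$cost_rules %||% c("m2", "m3", "m4", "m5"),
    price_files = raw$price_files, annual = annual,
    cohort_n = raw$cohort_n %||% 526,
    out_dir = raw$out_dir %||% tempfile("ddcea-run-"),
    seed = raw$seed %||% 1L,
    target_specificity = raw$target_specificity %||% 0.95,
    verbose = raw$verbose %||% TRUE
  )
}

# Analytic configuration only: output location and verbosity are
# presentation concerns and must not perturb the provenance hash.
config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$verbose <- NULL
  if (inherits(cfg$cohort_spec, "cohort_spec")) {
    cfg$cohort_spec <- "<in-memory cohort_spec>"
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: cohort (synthesize from spec, or load CSV), rule resolution,
#' diagnostic evaluation across scopes, cost analysis per currency, and
#' report writing.  Outputs in `config$out_dir`: `cohort.csv` (synthetic
#' runs only), `metrics.csv` / `metrics.json`, `savings.csv` /
#' `savings.json`, `summary.txt`, and `provenance.json` (seed, package
#' version, config echo and hash).  Outputs contain no timestamps: an
#' identical config and seed reproduces every file byte for byte.
#'
#' @param config A `run_config`.
#' @return A `dd_run_report` list with the cohort, resolved rules and
#'   thresholds, the metrics and savings tables, and provenance.
#' @export
run_vte_analysis <- function(config) {
  if (!inherits(config, "run_config")) {
    dd_error("config must be a run_config object", "ddcea_config_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))

  if (!is.null(config$cohort_csv)) {
    cohort <- read_cohort_csv(config$cohort_csv)
    synthetic <- FALSE
  } else {
    spec <- config$cohort_spec
    if (is.null(spec)) spec <- default_cohort_spec()
    if (is.character(spec)) spec <- read_cohort_spec(spec)
    cohort <- generate_cohort(spec, seed = config$seed)
    synthetic <- TRUE
    write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"))
  }
  n_vte <- sum(cohort$status != "none")
  say("stage cohort: %d patients (%d VTE / %d controls)%s",
      nrow(cohort), n_vte, nrow(cohort) - n_vte,
      if (synthetic) sprintf(", synthetic, seed %d", config$seed) else "")

  rules <- dd_rules(cohort, config$rules, config$target_specificity)
  thresholds <- vapply(rules, function(r) r$fixed_value %||% NA_real_,
                       numeric(1))
  say("stage rules: resolved thresholds %s",
      paste(sprintf("%s=%s", names(rules),
                    ifelse(is.na(thresholds), "f(age)",
                           sprintf("%.4g", thresholds))),
            collapse = " "))

  metrics <- evaluate_rules(cohort, rules)
  write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
            row.names = FALSE)
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  say("stage metrics: %d rows across %d scopes", nrow(metrics), 3L)

  prices <- if (is.null(config$price_files)) default_price_schedules() else {
    ps <- lapply(config$price_files, read_price_schedule)
    names(ps) <- vapply(ps, `[[`, character(1), "currency")
    ps
  }
  savings <- savings_table(cohort, rules[config$cost_rules],
                           rules[[config$reference]], prices,
                           cohort_n = config$cohort_n, annual = config$annual)
  write.csv(savings, file.path(config$out_dir, "savings.csv"),
            row.names = FALSE)
  jsonlite::write_json(savings, file.path(config$out_dir, "savings.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  say("stage cost: %d rule x currency rows, reference %s",
      nrow(savings), config$reference)

  prov_cfg <- config_as_list(config)
  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(prov_cfg, cfg_json, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  provenance <- list(
    package = "ddcea",
    version = as.character(packageVersion("ddcea")),
    seed = config$seed,
    synthetic_cohort = synthetic,
    config_hash = unname(tools::md5sum(cfg_json)),
    resolved_thresholds = as.list(thresholds)
  )
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  overall <- metrics[metrics$scope == "overall", ]
  summary_lines <- c(
    "D-dimer cut-off strategy evaluation",
    sprintf("cohort: %d patients, %d VTE (prevalence %d%%), %d controls",
            nrow(cohort), n_vte,
            round_half_up(100 * n_vte / nrow(cohort)),
            nrow(cohort) - n_vte),
    sprintf("reference strategy: %s", config$reference),
    "",
    "rule  threshold   sens%  spec%  FN",
    vapply(seq_len(nrow(overall)), function(i) {
      r <- overall[i, ]
      sprintf("%-4s  %-9s  %5d  %5d  %2d", r$rule_id,
              ifelse(is.na(r$threshold), "f(age)",
                     sprintf("%.3f", r$threshold)),
              round_half_up(100 * r$sensitivity),
              round_half_up(100 * r$specificity), r$n_false_neg)
    }, character(1)),
    "",
    "savings vs reference (display-rounded):",
    vapply(seq_len(nrow(savings)), function(i) {
      s <- savings[i, ]
      sprintf("%-4s %s: CTPA %d + CUS %d exams -> %s %s (annualized %s)",
              s$rule_id, s$currency, s$n_ctpa_saved, s$n_cus_saved,
              format(s$savings_total, big.mark = ","), s$currency,
              format(s$annualized, big.mark = ","))
    }, character(1))
  )
  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))

  structure(
    list(cohort = cohort, rules = rules, thresholds = thresholds,
         metrics = metrics, savings = savings, provenance = provenance,
         out_dir = config$out_dir),
    class = "dd_run_report"
  )
}

#' Flatten run reports into a tidy comparison table
#'
#' @param reports A list of `dd_run_report` objects (or a single one).
#' @param run_ids Optional labels; default `run1`, `run2`, ...
#' @return Long-format tibble with columns `run`, `rule_id`, `scope`,
#'   `metric`, `value`, suitable for plotting or diffing runs.
#' @export
compare_runs <- function(reports, run_ids = NULL) {
  if (inherits(reports, "dd_run_report")) reports <- list(reports)
  if (!length(reports)) {
    dd_error("need at least one run report", "ddcea_invalid_input")
  }
  run_ids <- run_ids %||% sprintf("run%d", seq_along(reports))
  out <- Map(function(rep, id) {
    m <- rep$metrics
    value_cols <- setdiff(names(m), c("rule_id", "scope"))
    do.call(rbind, lapply(value_cols, function(cl) {
      tibble::tibble(run = id, rule_id = m$rule_id, scope = m$scope,
                     metric = cl, value = as.numeric(m[[cl]]))
    }))
  }, reports, run_ids)
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- tibble::tibble(run = character(), rule_id = character(),
                          scope = character(), metric = character(),
                          value = numeric())
  }
  out
}
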
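# Fixture builders and independent brute-force oracles.

make_cohort <- function(d, status, age = 60, pathway = NULL,
                        pretest = "low") {
  n <- length(d)
  status <- rep_len(status, n)
  if (is.null(pathway)) {
    pathway <- ifelse(status == "PE", "CTPA",
                      ifelse(status == "DVT", "CUS", "CTPA"))
  }
  tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = rep_len(age, n),
    d_dimer = d,
    status = status,
    pathway = rep_len(pathway, n),
    pretest = rep_len(pretest, n)
  )
}

# Random mixed cohort with ties (values on a coarse grid).
random_cohort <- function(n_case, n_ctrl, grid = 0.5) {
  d_case <- round(rlnorm(n_case, log(4), 0.9) / grid) * grid + grid
  d_ctrl <- round(rlnorm(n_ctrl, log(0.6), 0.9) / grid) * grid + grid
  make_cohort(c(d_case, d_ctrl),
              c(rep("PE", n_case), rep("none", n_ctrl)),
              age = sample(18:100, n_case + n_ctrl, replace = TRUE))
}

# Pairwise-comparison AUC oracle: explicit double loop, ties get half credit.
brute_auc <- function(cases, controls) {
  s <- 0
  for (a in cases) {
    for (b in controls) s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(cases) * length(controls))
}

# Exhaustive Youden search: counts sensitivity/specificity from scratch at
# every observed threshold (plus Inf), returns the lowest maximizer.
brute_youden <- function(cohort) {
  cases <- cohort$d_dimer[cohort$status != "none"]
  ctrl <- cohort$d_dimer[cohort$status == "none"]
  best_t <- NA_real_
  best_j <- -Inf
  for (t in c(sort(unique(cohort$d_dimer)), Inf)) {
    sens <- sum(cases >= t) / length(cases)
    spec <- sum(ctrl < t) / length(ctrl)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}
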
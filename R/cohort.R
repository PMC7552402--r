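#' Simulate a clinical covariate table
#'
#' Generates per-sample covariates with the marginal structure of a COPD
#' case/control lung cohort: age, sex, current/ex smoking, pack-years,
#' FEV1 (% predicted), FEV1/FVC ratio and GOLD stage. COPD membership is by
#' construction: the first `n_copd` samples receive FEV1/FVC < 70, the rest
#' >= 70 (pre-bronchodilator convention). GOLD stage is derived from FEV1
#' %predicted (>= 80: 1, 50-79: 2, 30-49: 3, < 30: 4) and is `"none"` for
#' non-COPD samples. The marginal distributions are configuration, not
#' claims about any real cohort.
#'
#' @param n_samples Total samples.
#' @param n_copd Number of COPD samples (<= n_samples).
#' @param seed Integer seed.
#' @param n_cohorts Samples are assigned round-robin to this many cohorts
#'   (`cohort1`, `cohort2`, ...).
#' @param p_other_lung_disease Probability of flagging a sample with another
#'   lung disease (excluded downstream); default 0.
#' @return data.frame of class `covariate_table` with columns `sample_id`,
#'   `age`, `sex`, `smoking`, `pack_years`, `fev1_pct_pred`,
#'   `fev1_fvc_ratio`, `gold_stage`, `cohort`, `other_lung_disease`.
#' @export
simulate_cohort <- function(n_samples, n_copd, seed = 1L, n_cohorts = 3L,
                            p_other_lung_disease = 0) {
  if (!is_count(n_samples) || n_samples < 1)
    stop_invalid("n_samples must be a positive count")
  if (!is_count(n_copd) || n_copd > n_samples)
    stop_invalid("n_copd must be a count <= n_samples")
  set.seed(as.integer(seed))

  copd <- c(rep(TRUE, n_copd), rep(FALSE, n_samples - n_copd))
  age <- round(rnorm_trunc(n_samples, 63, 9, 41, 90), 1)
  sex <- ifelse(runif(n_samples) < ifelse(copd, 0.587, 0.559),
                "male", "female")
  smoking <- ifelse(runif(n_samples) < ifelse(copd, 0.304, 0.246),
                    "current", "ex")
  pack_years <- round(exp(rnorm(n_samples,
                                log(ifelse(copd, 41.5, 38)), 0.45)), 1)
  pack_years <- pmax(pack_years, 5)
  ratio <- ifelse(copd,
                  rnorm_trunc(n_samples, 58.33, 9.7, 25, 69.99),
                  rnorm_trunc(n_samples, 75.12, 4.3, 70, 95))
  fev1 <- ifelse(copd,
                 rnorm_trunc(n_samples, 62.17, 12.8, 15, 95),
                 rnorm_trunc(n_samples, 94.31, 13.7, 60, 140))
  gold <- ifelse(!copd, "none",
                 ifelse(fev1 >= 80, "1",
                        ifelse(fev1 >= 50, "2",
                               ifelse(fev1 >= 30, "3", "4"))))
  out <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    age = age, sex = sex, smoking = smoking, pack_years = pack_years,
    fev1_pct_pred = round(fev1, 2), fev1_fvc_ratio = round(ratio, 2),
    gold_stage = gold,
    cohort = sprintf("cohort%d", ((seq_len(n_samples) - 1L) %% n_cohorts) + 1L),
    other_lung_disease = runif(n_samples) < p_other_lung_disease,
    stringsAsFactors = FALSE
  )
  class(out) <- c("covariate_table", "data.frame")
  out
}
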
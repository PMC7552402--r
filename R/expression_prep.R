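# Cohort definition, robust covariate adjustment, group comparison and
# lung-function correlation.

#' Classify samples into COPD / non-COPD / excluded
#'
#' Inclusion filters are applied first: a sample is excluded when age is not
#' strictly greater than 40 years, pack-years are below 5, smoking status is
#' `never`, another lung disease is flagged, or a required field is missing.
#' Among included samples, COPD is FEV1/FVC < 70 and non-COPD is
#' FEV1/FVC >= 70 (boundary inclusive on the non-COPD side;
#' pre-bronchodilator values assumed).
#'
#' @param covariates A covariate table (see [simulate_cohort()]).
#' @return data.frame `sample_id`, `label` (`COPD`, `non-COPD`, `excluded`),
#'   `reason` (NA unless excluded). Every sample receives exactly one label.
#' @export
classify_cohort <- function(covariates) {
  n <- nrow(covariates)
  label <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  required <- c("age", "smoking", "pack_years", "fev1_fvc_ratio")
  for (i in seq_len(n)) {
    row <- covariates[i, ]
    miss <- required[vapply(required, function(f) {
      is.null(row[[f]]) || is.na(row[[f]])
    }, logical(1))]
    if (length(miss)) {
      label[i] <- "excluded"
      reason[i] <- paste0("missing field: ", paste(miss, collapse = ","))
    } else if (isTRUE(row$other_lung_disease)) {
      label[i] <- "excluded"; reason[i] <- "other lung disease"
    } else if (row$age <= 40) {
      label[i] <- "excluded"; reason[i] <- "age <= 40"
    } else if (row$smoking == "never") {
      label[i] <- "excluded"; reason[i] <- "never smoker"
    } else if (row$pack_years < 5) {
      label[i] <- "excluded"; reason[i] <- "pack-years < 5"
    } else if (row$fev1_fvc_ratio < 70) {
      label[i] <- "COPD"
    } else {
      label[i] <- "non-COPD"
    }
  }
  data.frame(sample_id = covariates$sample_id, label = label,
             reason = reason, stringsAsFactors = FALSE)
}

# Design matrix for covariate adjustment / QTL fitting. Collinear columns
# (zero variance after the intercept) are dropped with a warning.
covariate_design <- function(covariates, smoking_coding = c("current_ex",
                                                            "current")) {
  smoking_coding <- match.arg(smoking_coding)
  X <- cbind(
    `(Intercept)` = 1,
    age = covariates$age,
    sex_male = as.numeric(covariates$sex == "male"),
    smoking_current = as.numeric(covariates$smoking == "current")
  )
  # current_ex and current coincide when the cohort holds only current/ex
  # smokers (never-smokers are excluded upstream); the column is the
  # current-smoking indicator either way.
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(col) {
    length(unique(col)) > 1
  }))
  if (!all(keep)) {
    warning("dropping collinear covariate term(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X[, keep, drop = FALSE]
}

#' Adjust an expression matrix for clinical covariates
#'
#' Per feature, fits `value ~ intercept + age + sex + smoking` with a Huber
#' M-estimator (tuning constant 1.345, iterated to relative tolerance 1e-9)
#' and returns `residual + fitted intercept`, so the unit and location of
#' the input (e.g. log2 intensity) are preserved. Adjusting an already
#' adjusted matrix leaves it essentially unchanged.
#'
#' @param expr samples x features numeric matrix (rownames = sample ids).
#' @param covariates Covariate table aligned with the rows of `expr`.
#' @return Adjusted matrix of the same shape.
#' @export
adjust_expression <- function(expr, covariates) {
  expr <- as.matrix(expr)
  if (nrow(expr) != nrow(covariates))
    stop("expression rows and covariate rows differ")
  X <- covariate_design(covariates)
  out <- expr
  for (j in seq_len(ncol(expr))) {
    y <- expr[, j]
    # a (near-)perfect linear fit has no residual scale for the
    # M-estimator to work with; the OLS solution is already the answer
    ols <- stats::lm.fit(X, y)
    if (max(abs(ols$residuals)) < 1e-10 * max(1, max(abs(y)))) {
      out[, j] <- ols$residuals + ols$coefficients[["(Intercept)"]]
      next
    }
    fit <- MASS::rlm(x = X, y = y, psi = MASS::psi.huber,
                     k = 1.345, maxit = 200, acc = 1e-9)
    out[, j] <- stats::residuals(fit) + coef(fit)[["(Intercept)"]]
  }
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Computes the U statistic with average ranks for ties. For group sizes
#' both <= `exact_max` the two-sided p-value is obtained by exhaustive
#' enumeration of all group assignments of the observed pooled values
#' (handles ties exactly): `p = min(1, 2 * min(P(U <= u), P(U >= u)))`.
#' Larger groups use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Exact-enumeration threshold on each group size.
#' @return list with `U` (statistic for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop_invalid("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(ii) {
      sum(r[ii]) - n1 * (n1 + 1) / 2
    })
    tol <- 1e-9
    p_le <- mean(us <= U + tol)
    p_ge <- mean(us >= U - tol)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "degenerate"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(U = U, p_value = p, method = method)
}

#' Compare expression between groups with Mann-Whitney U tests
#'
#' Tests each feature between COPD and non-COPD (labels from
#' [classify_cohort()]), and optionally each GOLD stage against non-COPD.
#'
#' @param adjusted samples x features matrix (typically from
#'   [adjust_expression()]).
#' @param labels data.frame from [classify_cohort()] aligned to rows, or a
#'   character vector of labels.
#' @param covariates Optional covariate table (needed for the per-GOLD-stage
#'   breakdown).
#' @param by_gold_stage Also compare each GOLD stage vs non-COPD.
#' @return data.frame of class `diffexp_result` with columns `feature`,
#'   `comparison`, `n1`, `n2`, `median1`, `median2`, `U`, `p_value`.
#'   Comparisons with an empty group are skipped with a warning.
#' @export
compare_groups <- function(adjusted, labels, covariates = NULL,
                           by_gold_stage = FALSE) {
  if (is.data.frame(labels)) labels <- labels$label
  adjusted <- as.matrix(adjusted)
  groups <- list(`COPD_vs_nonCOPD` = list(g1 = labels == "COPD",
                                          g2 = labels == "non-COPD"))
  if (by_gold_stage) {
    if (is.null(covariates))
      stop("covariates required for the GOLD-stage breakdown")
    for (st in sort(setdiff(unique(covariates$gold_stage), "none"))) {
      groups[[paste0("GOLD", st, "_vs_nonCOPD")]] <-
        list(g1 = labels == "COPD" & covariates$gold_stage == st,
             g2 = labels == "non-COPD")
    }
  }
  rows <- list()
  for (cmp in names(groups)) {
    g1 <- groups[[cmp]]$g1; g2 <- groups[[cmp]]$g2
    if (!any(g1) || !any(g2)) {
      warning("comparison ", cmp, " skipped: empty group")
      next
    }
    for (j in seq_len(ncol(adjusted))) {
      mw <- mann_whitney(adjusted[g1, j], adjusted[g2, j])
      rows[[length(rows) + 1L]] <- data.frame(
        feature = colnames(adjusted)[j] %||% as.character(j),
        comparison = cmp, n1 = sum(g1), n2 = sum(g2),
        median1 = median(adjusted[g1, j]), median2 = median(adjusted[g2, j]),
        U = mw$U, p_value = mw$p_value, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("diffexp_result", "data.frame")
  out
}

#' Spearman correlation of expression with lung function
#'
#' Rank correlation (average ranks for ties) of each feature with FEV1
#' %predicted and FEV1/FVC, overall and per group. Constant inputs yield NA
#' with the reason recorded.
#'
#' @param adjusted samples x features matrix.
#' @param covariates Covariate table aligned to rows.
#' @param labels Optional labels from [classify_cohort()] for per-group
#'   correlations.
#' @return data.frame `feature`, `measure`, `group`, `rho`, `p_value`, `n`.
#' @export
correlate_lung_function <- function(adjusted, covariates, labels = NULL) {
  adjusted <- as.matrix(adjusted)
  measures <- c(fev1_pct_pred = "fev1_pct_pred",
                fev1_fvc_ratio = "fev1_fvc_ratio")
  if (is.data.frame(labels)) labels <- labels$label
  groups <- list(all = rep(TRUE, nrow(adjusted)))
  if (!is.null(labels)) {
    groups$COPD <- labels == "COPD"
    groups$`non-COPD` <- labels == "non-COPD"
  }
  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (sum(sel) < 3) next
    for (m in names(measures)) {
      v <- covariates[[measures[m]]][sel]
      for (j in seq_len(ncol(adjusted))) {
        y <- adjusted[sel, j]
        if (sd(v) == 0 || sd(y) == 0) {
          rho <- NA_real_; p <- NA_real_
        } else {
          ct <- suppressWarnings(
            cor.test(v, y, method = "spearman", exact = FALSE))
          rho <- unname(ct$estimate); p <- ct$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          feature = colnames(adjusted)[j] %||% as.character(j),
          measure = m, group = g, rho = rho, p_value = p, n = sum(sel),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
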
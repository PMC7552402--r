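# Cis-eQTL / spliceQTL engine: window selection, MAF filtering, additive
# dosage model, inverse-variance-weighted meta-analysis, multiplicity
# control.

#' Select SNPs within a cis window around a feature anchor
#'
#' @param anchor_chrom,anchor_pos Chromosome and position of the feature
#'   anchor (e.g. the probe binding site or junction position).
#' @param snps data.frame with `snp_id`, `chrom`, `position`.
#' @param window_bp Window half-width; SNPs with
#'   `|position - anchor| <= window_bp` on the same chromosome are kept
#'   (boundary inclusive). Default 1 Mb.
#' @return The subset of `snps` (possibly empty) in input order.
#' @export
select_cis_snps <- function(anchor_chrom, anchor_pos, snps,
                            window_bp = 1e6) {
  keep <- snps$chrom == anchor_chrom &
    abs(snps$position - anchor_pos) <= window_bp
  snps[keep, , drop = FALSE]
}

#' Remove SNPs below a minor allele frequency threshold
#'
#' MAF is computed from the mean dosage / 2, folded at 0.5. SNPs with
#' `MAF < threshold` are removed (strict inequality: a SNP at exactly the
#' threshold is kept); monomorphic SNPs (MAF 0) always go.
#'
#' @param genotypes A `genotype_matrix`.
#' @param threshold MAF threshold (default 0.05).
#' @return Filtered `genotype_matrix` with refreshed `maf` column.
#' @export
filter_maf <- function(genotypes, threshold = 0.05) {
  maf <- snp_maf(genotypes$dosages)
  keep <- maf >= threshold
  structure(list(
    samples = genotypes$samples,
    snps = transform(genotypes$snps[keep, , drop = FALSE],
                     maf = maf[keep]),
    dosages = genotypes$dosages[, keep, drop = FALSE]
  ), class = "genotype_matrix")
}

#' Fit one additive-dosage association model
#'
#' Ordinary least squares of `value ~ dosage + age + sex + smoking`
#' (covariate columns built from the covariate table; pass `covariates =
#' NULL` for a dosage-only model). Missing values are handled by pairwise
#' deletion. The genotype of high expression is the alt/alt homozygote when
#' the dosage effect is positive, ref/ref otherwise.
#'
#' @param values Per-sample feature values.
#' @param dosage Per-sample alt-allele dosages (0..2, missing allowed).
#' @param covariates Covariate table aligned to samples, or NULL.
#' @param snp_id,feature_id,cohort Identifiers carried into the result.
#' @param ref,alt Allele labels used for the genotype-of-high-expression
#'   string (defaults `"ref"`/`"alt"`).
#' @param smoking_coding Passed to the design builder; the spliceQTL path
#'   uses the current-smoking indicator.
#' @return One-row data.frame of class `qtl_result`: `snp_id`,
#'   `feature_id`, `cohort`, `beta`, `se`, `p_value`, `n`,
#'   `genotype_high_expression`, `testable`. Insufficient samples or zero
#'   dosage variance give `testable = FALSE` with NA estimates.
#' @export
fit_qtl <- function(values, dosage, covariates = NULL,
                    snp_id = NA_character_, feature_id = NA_character_,
                    cohort = NA_character_, ref = "ref", alt = "alt",
                    smoking_coding = "current_ex") {
  X <- if (is.null(covariates)) {
    matrix(1, length(values), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariate_design(covariates, smoking_coding = smoking_coding)
  }
  ok <- complete.cases(cbind(values, dosage, X))
  y <- values[ok]
  d <- dosage[ok]
  Xc <- cbind(dosage = d, X[ok, , drop = FALSE])
  n <- length(y)
  untestable <- function() {
    data.frame(snp_id = snp_id, feature_id = feature_id, cohort = cohort,
               beta = NA_real_, se = NA_real_, p_value = NA_real_, n = n,
               genotype_high_expression = NA_character_, testable = FALSE,
               ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  if (n < ncol(Xc) + 2 || stats::var(d) == 0) {
    out <- untestable()
    class(out) <- c("qtl_result", "data.frame")
    return(out)
  }
  qr_x <- qr(Xc)
  if (qr_x$rank < ncol(Xc)) {
    out <- untestable()
    class(out) <- c("qtl_result", "data.frame")
    return(out)
  }
  cf <- qr.coef(qr_x, y)
  res <- y - Xc %*% cf
  df <- n - ncol(Xc)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[1, 1])
  beta <- cf[["dosage"]]
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  hi <- if (beta > 0) paste0(alt, alt) else paste0(ref, ref)
  out <- data.frame(snp_id = snp_id, feature_id = feature_id,
                    cohort = cohort, beta = beta, se = se,
                    p_value = max(p, .Machine$double.xmin), n = n,
                    genotype_high_expression = hi, testable = TRUE,
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  class(out) <- c("qtl_result", "data.frame")
  out
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Combines per-cohort results for one SNP-feature pair:
#' `meta_beta = sum(w_c * beta_c) / sum(w_c)` with `w_c = 1/se_c^2`,
#' `meta_se = 1/sqrt(sum(w_c))`, Wald p-value. A random-effects
#' (DerSimonian-Laird) combination is available behind `method`.
#' Untestable cohorts are ignored; with none left the result is flagged
#' untestable.
#'
#' @param per_cohort data.frame of `qtl_result` rows (rbind-ed), or a list
#'   of them.
#' @param method `"fixed"` (default) or `"random"`.
#' @return One-row data.frame of class `meta_qtl_result`: `snp_id`,
#'   `feature_id`, `meta_beta`, `meta_se`, `meta_p`, `n_total`,
#'   `n_cohorts`, `genotype_high_expression`, `testable`.
#' @export
meta_qtl <- function(per_cohort, method = c("fixed", "random")) {
  method <- match.arg(method)
  if (is.list(per_cohort) && !is.data.frame(per_cohort))
    per_cohort <- do.call(rbind, per_cohort)
  ok <- per_cohort$testable & !is.na(per_cohort$se) & per_cohort$se > 0
  d <- per_cohort[ok, , drop = FALSE]
  base <- data.frame(
    snp_id = per_cohort$snp_id[1], feature_id = per_cohort$feature_id[1],
    meta_beta = NA_real_, meta_se = NA_real_, meta_p = NA_real_,
    n_total = sum(per_cohort$n), n_cohorts = nrow(d),
    genotype_high_expression = NA_character_, testable = FALSE,
    stringsAsFactors = FALSE
  )
  if (nrow(d) == 0) {
    class(base) <- c("meta_qtl_result", "data.frame")
    return(base)
  }
  w <- 1 / d$se^2
  if (method == "random" && nrow(d) > 1) {
    mb_f <- sum(w * d$beta) / sum(w)
    Q <- sum(w * (d$beta - mb_f)^2)
    tau2 <- max(0, (Q - (nrow(d) - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w <- 1 / (d$se^2 + tau2)
  }
  mb <- sum(w * d$beta) / sum(w)
  ms <- 1 / sqrt(sum(w))
  mp <- 2 * pnorm(-abs(mb / ms))
  hi <- if (mb > 0) paste0(d$alt[1], d$alt[1]) else paste0(d$ref[1], d$ref[1])
  base$meta_beta <- mb
  base$meta_se <- ms
  base$meta_p <- max(mp, .Machine$double.xmin)
  base$genotype_high_expression <- hi
  base$testable <- TRUE
  class(base) <- c("meta_qtl_result", "data.frame")
  base
}

#' Fill Bonferroni and BH-FDR columns on meta results
#'
#' `bonferroni_p = min(1, m * p)` and Benjamini-Hochberg FDR over the same
#' family, where the family is either all SNP-feature tests in the run
#' (default) or the tests of each feature's cis window
#' (`family = "per_feature"`). Untestable rows are excluded from `m`.
#' The significance flag is `bonferroni_p < alpha`.
#'
#' @param results data.frame of meta results (`meta_p` column).
#' @param family `"global"` or `"per_feature"`.
#' @param alpha Significance level for the flag (default 0.05).
#' @return `results` with `bonferroni_p`, `fdr`, `significant` filled.
#' @export
adjust_multiplicity <- function(results, family = c("global", "per_feature"),
                                alpha = 0.05) {
  family <- match.arg(family)
  if (!nrow(results)) stop_invalid("empty result list")
  results$bonferroni_p <- NA_real_
  results$fdr <- NA_real_
  idx_groups <- if (family == "global") {
    list(which(results$testable))
  } else {
    split(which(results$testable), results$feature_id[results$testable])
  }
  for (idx in idx_groups) {
    m <- length(idx)
    if (!m) next
    results$bonferroni_p[idx] <- pmin(1, m * results$meta_p[idx])
    results$fdr[idx] <- p.adjust(results$meta_p[idx], method = "BH")
  }
  results$significant <- !is.na(results$bonferroni_p) &
    results$bonferroni_p < alpha
  results
}

#' Run the full cis-QTL scan across cohorts
#'
#' For each feature: select SNPs in the cis window around its anchor, MAF-
#' filter within each cohort's samples, fit the covariate-adjusted additive
#' dosage model per cohort, combine cohorts by fixed-effect IVW
#' meta-analysis, and control multiplicity. The spliceQTL path is this same
#' engine applied to normalized junction features with
#' `smoking_coding = "current"`.
#'
#' @param expr samples x features matrix.
#' @param genotypes A `genotype_matrix` covering the same samples.
#' @param covariates Covariate table (must have a `cohort` column).
#' @param anchors data.frame `feature_id`, `chrom`, `position`.
#' @param window_bp Cis window half-width (default 1 Mb).
#' @param maf MAF threshold (default 0.05).
#' @param alpha Significance level.
#' @param family Multiplicity family, see [adjust_multiplicity()].
#' @param smoking_coding Covariate coding, see [fit_qtl()].
#' @param meta_method `"fixed"` or `"random"`.
#' @return list with `meta` (meta results + multiplicity columns) and
#'   `per_cohort` (all cohort-level fits), both data.frames.
#' @export
qtl_scan <- function(expr, genotypes, covariates, anchors,
                     window_bp = 1e6, maf = 0.05, alpha = 0.05,
                     family = "global", smoking_coding = "current_ex",
                     meta_method = "fixed") {
  expr <- as.matrix(expr)
  stopifnot(nrow(expr) == length(genotypes$samples))
  cohorts <- sort(unique(covariates$cohort))
  per_rows <- list()
  meta_rows <- list()
  for (f in anchors$feature_id) {
    a <- anchors[anchors$feature_id == f, ]
    cis <- select_cis_snps(a$chrom, a$position, genotypes$snps, window_bp)
    for (s in cis$snp_id) {
      info <- genotypes$snps[genotypes$snps$snp_id == s, ]
      fits <- list()
      for (co in cohorts) {
        sel <- covariates$cohort == co
        gt_co <- structure(list(
          samples = genotypes$samples[sel],
          snps = info,
          dosages = genotypes$dosages[sel, s, drop = FALSE]
        ), class = "genotype_matrix")
        if (snp_maf(gt_co$dosages) < maf) next  # MAF filter per cohort
        fits[[co]] <- fit_qtl(
          expr[sel, f], gt_co$dosages[, 1], covariates[sel, ],
          snp_id = s, feature_id = f, cohort = co,
          ref = info$ref, alt = info$alt, smoking_coding = smoking_coding
        )
      }
      if (!length(fits)) next
      per <- do.call(rbind, fits)
      per_rows[[length(per_rows) + 1L]] <- per
      meta_rows[[length(meta_rows) + 1L]] <- meta_qtl(per,
                                                      method = meta_method)
    }
  }
  if (!length(meta_rows)) {
    return(list(meta = data.frame(), per_cohort = data.frame()))
  }
  meta <- adjust_multiplicity(do.call(rbind, meta_rows), family = family,
                              alpha = alpha)
  list(meta = meta, per_cohort = do.call(rbind, per_rows))
}
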
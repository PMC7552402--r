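#' Effect specification for the abundance generator
#'
#' Parameterizes the generative model for splice-variant abundances:
#' log-abundance of variant v in sample i is
#' `log(baseline_v) + sum_snp beta[snp, v] * dosage_i(snp)
#'  + disease_shift_v * 1[COPD_i] + coef_age_v * (age_i - 60)
#'  + coef_sex_male_v * 1[male_i] + coef_smoking_current_v * 1[current_i]
#'  + Normal(0, noise_sd)`.
#' Age is centered at 60 years so baselines stay interpretable as the
#' abundance of a 60-year-old female ex-smoker without COPD at dosage 0.
#'
#' @param variants Named list (one entry per variant id) of lists with
#'   `baseline` (> 0, expected count scale), `disease_shift` (log-scale COPD
#'   effect), `beta` (named numeric, per-SNP additive log-scale effect per
#'   alt-allele dosage; may be empty), and optional covariate coefficients
#'   `coef_age`, `coef_sex_male`, `coef_smoking_current` (default 0).
#' @param noise_sd Log-scale residual standard deviation (>= 0).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(variants, noise_sd = 0.25) {
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_invalid("noise_sd must be >= 0")
  for (nm in names(variants)) {
    v <- variants[[nm]]
    if (is.null(v$baseline) || v$baseline <= 0)
      stop_invalid("variant ", nm, ": baseline must be > 0")
    variants[[nm]]$disease_shift <- v$disease_shift %||% 0
    variants[[nm]]$beta <- v$beta %||% numeric()
    variants[[nm]]$coef_age <- v$coef_age %||% 0
    variants[[nm]]$coef_sex_male <- v$coef_sex_male %||% 0
    variants[[nm]]$coef_smoking_current <- v$coef_smoking_current %||% 0
  }
  structure(list(variants = variants, noise_sd = noise_sd),
            class = "effect_spec")
}

#' Default "flip" effect specification
#'
#' The planted scenario in which a single SNP pushes the coding variant up
#' and the non-coding (intron-retaining) variants down strongly enough that
#' junction-restricted (probe-detected) abundance rises with dosage while
#' total abundance falls. Per alt-allele dosage: coding `V1` +0.35
#' (baseline 10), intron-2-retaining `V2` -0.35 (baseline 40),
#' intron-1-retaining `V3` -0.05 (baseline 20). With these values both
#' probe-detected abundance (V1+V3) and total abundance (V1+V2+V3) are
#' monotone in dosage, with opposite directions, at any allele frequency,
#' and the total keeps falling through dosage 2 even after the COPD shift
#' raises the coding variant's average level. The COPD shift gives higher
#' disease-group expression of the probe-detected signal.
#'
#' @param snp_id Identifier of the focal SNP the betas attach to.
#' @param disease_shift_coding Log-scale COPD shift on the coding variant.
#' @param noise_sd Log-scale residual SD.
#' @return An [effect_spec()].
#' @export
default_flip_spec <- function(snp_id = "rs_flip", disease_shift_coding = 0.3,
                              noise_sd = 0.25) {
  effect_spec(
    variants = list(
      V1 = list(baseline = 10, beta = setNames(+0.35, snp_id),
                disease_shift = disease_shift_coding),
      V2 = list(baseline = 40, beta = setNames(-0.35, snp_id)),
      V3 = list(baseline = 20, beta = setNames(-0.05, snp_id))
    ),
    noise_sd = noise_sd
  )
}

#' Null effect specification
#'
#' All genetic and disease effects zero; used for global-null calibration.
#'
#' @param noise_sd Log-scale residual SD.
#' @param baselines Named baseline abundances per variant.
#' @return An [effect_spec()].
#' @export
null_effect_spec <- function(noise_sd = 0.25,
                             baselines = c(V1 = 10, V2 = 30, V3 = 20)) {
  effect_spec(
    variants = lapply(as.list(baselines), function(b) list(baseline = b)),
    noise_sd = noise_sd
  )
}

#' Simulate splice-variant abundances
#'
#' Draws per-sample abundances of each splice variant from the log-linear
#' model described in [effect_spec()]. Abundances are strictly positive.
#'
#' @param genotypes A `genotype_matrix` (samples must match `covariates`).
#' @param covariates A covariate table from [simulate_cohort()] (COPD status
#'   is taken as FEV1/FVC < 70).
#' @param gene A [gene_model()]; `spec` must cover every variant of it.
#' @param spec An [effect_spec()].
#' @param seed Integer seed.
#' @return samples x variants numeric matrix of abundances.
#' @export
simulate_variant_abundances <- function(genotypes, covariates, gene, spec,
                                        seed = 1L) {
  missing_v <- setdiff(names(gene$variants), names(spec$variants))
  if (length(missing_v))
    stop("effect_spec missing entries for variant(s): ",
         paste(missing_v, collapse = ", "))
  if (!identical(genotypes$samples, covariates$sample_id))
    stop("genotype and covariate samples do not match")
  set.seed(as.integer(seed))
  n <- length(genotypes$samples)
  vn <- names(gene$variants)
  copd <- as.numeric(covariates$fev1_fvc_ratio < 70)
  male <- as.numeric(covariates$sex == "male")
  current <- as.numeric(covariates$smoking == "current")
  agec <- covariates$age - 60

  out <- matrix(NA_real_, n, length(vn),
                dimnames = list(genotypes$samples, vn))
  for (v in vn) {
    sv <- spec$variants[[v]]
    eta <- rep(log(sv$baseline), n)
    if (length(sv$beta)) {
      for (s in names(sv$beta)) {
        eta <- eta + sv$beta[[s]] * snp_dosage(genotypes, s)
      }
    }
    eta <- eta + sv$disease_shift * copd + sv$coef_age * agec +
      sv$coef_sex_male * male + sv$coef_smoking_current * current
    noise <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else rep(0, n)
    out[, v] <- exp(eta + noise)
  }
  out
}

#' Expected abundances at fixed dosages (no noise)
#'
#' Evaluates the log-linear means of an [effect_spec()] at given focal-SNP
#' dosages with covariate and disease terms at reference levels. Useful for
#' analytic sign checks of the planted direction-flip mechanism.
#'
#' @param spec An [effect_spec()].
#' @param snp_id Focal SNP.
#' @param dosages Numeric dosages to evaluate at (default 0:2).
#' @return dosages x variants matrix of expected abundances.
#' @export
expected_abundances <- function(spec, snp_id, dosages = 0:2) {
  vn <- names(spec$variants)
  out <- matrix(NA_real_, length(dosages), length(vn),
                dimnames = list(as.character(dosages), vn))
  for (v in vn) {
    sv <- spec$variants[[v]]
    b <- if (snp_id %in% names(sv$beta)) sv$beta[[snp_id]] else 0
    out[, v] <- sv$baseline * exp(b * dosages)
  }
  out
}
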
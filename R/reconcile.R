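# Direction-of-effect reconciliation between measurement modes.

#' Direction-of-effect profile of a SNP across measurement modes
#'
#' Fits the covariate-adjusted additive dosage model for the same SNP
#' against three measurement modes of one gene: probe-style
#' junction-restricted log2 intensity (`probe`), log2 total FPKM (`total`)
#' and each normalized junction's split-read values (`junction:<key>`).
#' The flip flag is TRUE when both the probe and total effects pass the
#' significance gate (default p < 0.05 in each) with opposite signs, FALSE
#' when both pass with the same sign, and NA when either mode is untestable
#' or fails the gate.
#'
#' @param snp_id SNP identifier; must pass the MAF filter (error otherwise).
#' @param measurements A `measurement_set` from
#'   [simulate_measurement_set()] (or a list with `probe_log2`,
#'   `total_fpkm`, `junction_norm`).
#' @param genotypes A `genotype_matrix`.
#' @param covariates Covariate table aligned to samples.
#' @param alpha Significance gate for declaring a flip.
#' @param maf MAF threshold the SNP must pass.
#' @return Object of class `direction_report`: list with `snp_id`, `modes`
#'   (data.frame `mode`, `beta`, `se`, `p_value`, `n`,
#'   `genotype_high_expression`, `testable`), `flip_flag`, `alpha`.
#' @export
direction_profile <- function(snp_id, measurements, genotypes, covariates,
                              alpha = 0.05, maf = 0.05) {
  dosage <- snp_dosage(genotypes, snp_id)
  if (snp_maf(cbind(dosage)) < maf)
    stop_invalid("SNP ", snp_id, " fails the MAF filter (< ", maf, ")")
  info <- genotypes$snps[genotypes$snps$snp_id == snp_id, ]
  fit_mode <- function(values, feature_id) {
    fit_qtl(values, dosage, covariates, snp_id = snp_id,
            feature_id = feature_id, ref = info$ref, alt = info$alt,
            smoking_coding = "current")
  }
  rows <- list(fit_mode(measurements$probe_log2, "probe"),
               fit_mode(log2(measurements$total_fpkm), "total"))
  jn <- measurements$junction_norm
  if (!is.null(jn)) {
    for (k in colnames(jn)) {
      rows[[length(rows) + 1L]] <- fit_mode(jn[, k], paste0("junction:", k))
    }
  }
  modes <- do.call(rbind, rows)
  modes$mode <- modes$feature_id
  probe <- modes[modes$mode == "probe", ]
  total <- modes[modes$mode == "total", ]
  flip <- NA
  if (probe$testable && total$testable &&
      probe$p_value < alpha && total$p_value < alpha) {
    flip <- sign(probe$beta) != sign(total$beta)
  }
  structure(list(
    snp_id = snp_id,
    modes = modes[, c("mode", "beta", "se", "p_value", "n",
                      "genotype_high_expression", "testable")],
    flip_flag = flip, alpha = alpha
  ), class = "direction_report")
}

#' @export
print.direction_report <- function(x, ...) {
  cat(sprintf("<direction_report> %s (gate p < %g)\n", x$snp_id, x$alpha))
  m <- x$modes
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-24s beta %+ .4f  p %.3g  high: %s\n", m$mode[i],
                m$beta[i], m$p_value[i], m$genotype_high_expression[i]))
  }
  cat("  flip (probe vs total):",
      if (is.na(x$flip_flag)) "undetermined" else x$flip_flag, "\n")
  invisible(x)
}

# TSV-ready form of a direction report.
direction_report_table <- function(dr) {
  cbind(snp_id = dr$snp_id, dr$modes,
        flip_flag = ifelse(is.na(dr$flip_flag), NA, dr$flip_flag))
}
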
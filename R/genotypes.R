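#' Simulate genotype dosages with LD-block structure
#'
#' Draws alternate-allele dosages (0..2) under Hardy-Weinberg proportions.
#' LD within a declared block is induced by a block copula: each sample
#' haplotype draws one shared latent uniform per block, and each SNP in the
#' block keeps that latent with probability `q` (otherwise redraws its own
#' uniform), with `q = r2^(1/4)` so that the pairwise dosage r-squared between
#' block members is the requested `within_block_r2`. Independent SNPs are
#' mutually uncorrelated in expectation.
#'
#' @param n_samples Number of samples (>= 2).
#' @param block_spec List of blocks, each a list/vector with `n_snps`, `maf`,
#'   `within_block_r2`.
#' @param n_independent Number of additional independent SNPs.
#' @param seed Integer seed; identical seed gives bitwise-identical output.
#' @param chrom Chromosome name for all SNPs.
#' @param start_pos,spacing_bp Genomic position of the first SNP and spacing
#'   between consecutive SNPs (positions strictly increasing).
#' @param independent_mafs Optional MAF vector for the independent SNPs
#'   (defaults to draws from U(0.1, 0.5)).
#' @param independent_ids Optional identifiers for the independent SNPs.
#' @return An object of class `genotype_matrix`: list with `samples`,
#'   `snps` (data.frame `snp_id`, `chrom`, `position`, `ref`, `alt`, `maf`,
#'   `block`) and `dosages` (samples x SNPs matrix).
#' @export
simulate_genotypes <- function(n_samples, block_spec = list(),
                               n_independent = 0L, seed = 1L,
                               chrom = "chr22", start_pos = 23400000L,
                               spacing_bp = 40000L,
                               independent_mafs = NULL,
                               independent_ids = NULL) {
  if (!is_count(n_samples) || n_samples < 2)
    stop_invalid("n_samples must be a count >= 2")
  if (!is_count(n_independent))
    stop_invalid("n_independent must be a non-negative count")
  for (b in block_spec) {
    b <- as.list(b)
    if (!is_count(b$n_snps) || b$n_snps < 1)
      stop_invalid("block n_snps must be a positive count")
    if (!is.numeric(b$maf) || b$maf <= 0 || b$maf > 0.5)
      stop_invalid("maf must be in (0, 0.5]")
    if (!is.numeric(b$within_block_r2) || b$within_block_r2 < 0 ||
        b$within_block_r2 > 1)
      stop_invalid("within_block_r2 must be in [0, 1]")
  }
  set.seed(as.integer(seed))

  samples <- sprintf("S%04d", seq_len(n_samples))
  alleles <- c("A", "C", "G", "T")
  snp_rows <- list()
  dosage_cols <- list()

  draw_block <- function(n_snps, maf, r2, ids, block_label) {
    q <- r2^(1 / 4)
    hap <- function() {
      latent <- runif(n_samples)
      m <- matrix(NA_real_, n_samples, n_snps)
      for (j in seq_len(n_snps)) {
        keep <- runif(n_samples) < q
        u <- ifelse(keep, latent, runif(n_samples))
        m[, j] <- as.numeric(u < maf)
      }
      m
    }
    d <- hap() + hap()
    colnames(d) <- ids
    d
  }

  bi <- 0L
  for (b in block_spec) {
    b <- as.list(b)
    bi <- bi + 1L
    ids <- b$ids %||% sprintf("rs_b%d_%d", bi, seq_len(b$n_snps))
    d <- draw_block(b$n_snps, b$maf, b$within_block_r2, ids, bi)
    dosage_cols[[length(dosage_cols) + 1L]] <- d
    snp_rows[[length(snp_rows) + 1L]] <-
      data.frame(snp_id = ids, maf_target = b$maf, block = bi)
  }
  if (n_independent > 0) {
    mafs <- independent_mafs %||% runif(n_independent, 0.1, 0.5)
    if (length(mafs) != n_independent)
      stop_invalid("independent_mafs length must equal n_independent")
    ids <- independent_ids %||% sprintf("rs_i%d", seq_len(n_independent))
    d <- vapply(seq_len(n_independent),
                function(j) rbinom(n_samples, 2L, mafs[j]) + 0,
                numeric(n_samples))
    colnames(d) <- ids
    dosage_cols[[length(dosage_cols) + 1L]] <- d
    snp_rows[[length(snp_rows) + 1L]] <-
      data.frame(snp_id = ids, maf_target = mafs, block = NA_integer_)
  }
  if (!length(dosage_cols)) stop_invalid("no SNPs requested")

  dosages <- do.call(cbind, dosage_cols)
  rownames(dosages) <- samples
  info <- do.call(rbind, snp_rows)
  n_snps <- nrow(info)
  ra <- t(vapply(seq_len(n_snps),
                 function(i) sample(alleles, 2L), character(2)))
  snps <- data.frame(
    snp_id = info$snp_id, chrom = chrom,
    position = start_pos + (seq_len(n_snps) - 1L) * spacing_bp,
    ref = ra[, 1], alt = ra[, 2],
    maf = snp_maf(dosages), block = info$block,
    stringsAsFactors = FALSE
  )
  structure(list(samples = samples, snps = snps, dosages = dosages),
            class = "genotype_matrix")
}

# Sample MAF per SNP from mean dosage / 2, folded at 0.5; NA-tolerant.
snp_maf <- function(dosages) {
  f <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Subset a genotype matrix by SNP identifier
#' @param genotypes A `genotype_matrix`.
#' @param snp_ids Identifiers to keep, in this order.
#' @return A `genotype_matrix` restricted to those SNPs.
#' @export
subset_snps <- function(genotypes, snp_ids) {
  idx <- match(snp_ids, genotypes$snps$snp_id)
  if (anyNA(idx))
    stop("SNP(s) not found: ",
         paste(snp_ids[is.na(idx)], collapse = ", "))
  structure(list(samples = genotypes$samples,
                 snps = genotypes$snps[idx, , drop = FALSE],
                 dosages = genotypes$dosages[, idx, drop = FALSE]),
            class = "genotype_matrix")
}

#' Dosage vector for one SNP
#' @param genotypes A `genotype_matrix`.
#' @param snp_id SNP identifier.
#' @return Named numeric vector of dosages.
#' @export
snp_dosage <- function(genotypes, snp_id) {
  idx <- match(snp_id, genotypes$snps$snp_id)
  if (is.na(idx)) stop("SNP not found: ", snp_id)
  genotypes$dosages[, idx]
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%s:%s-%s)\n",
              length(x$samples), nrow(x$snps), x$snps$chrom[1],
              format(min(x$snps$position), big.mark = ","),
              format(max(x$snps$position), big.mark = ",")))
  invisible(x)
}
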
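# Linkage disequilibrium from genotype dosages: pairwise r2, greedy block
# clustering of ranked SNPs, proxy lookup, GWAS catalog cross-reference.
# The r2 estimator is the squared Pearson correlation of dosages (composite
# LD); haplotype-phase estimators are out of scope since only dosages exist
# in this data model.

#' Pairwise LD r-squared from dosages
#'
#' Squared Pearson correlation over pairwise-complete samples. Monomorphic
#' input (or fewer than 3 complete pairs) is undefined and returns NA.
#'
#' @param dosage_a,dosage_b Per-sample dosage vectors.
#' @return r-squared in \[0, 1\], or NA. Symmetric in its arguments.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Cluster ranked SNPs into LD blocks
#'
#' Greedy clustering: the most significant unassigned SNP becomes a block
#' representative; every unassigned SNP with `r2 > threshold` to it joins
#' the block; repeat. Representatives without members become independent
#' signals. Blocks and independent signals partition the input.
#'
#' @param snps Either a character vector of SNP ids already ranked by
#'   ascending meta p-value, or a data.frame with `snp_id` and `meta_p`
#'   (ties broken by genomic position).
#' @param genotypes A `genotype_matrix` containing every listed SNP (an
#'   error names any that are missing).
#' @param threshold Block membership requires `r2 > threshold` (strict;
#'   default 0.8).
#' @return Object of class `ld_block_set`: list with `blocks` (list of
#'   lists: `representative`, `members`, `r2` of members to the
#'   representative) and `independent` (character vector).
#' @export
cluster_ld_blocks <- function(snps, genotypes, threshold = 0.8) {
  if (is.data.frame(snps)) {
    pos <- genotypes$snps$position[match(snps$snp_id,
                                         genotypes$snps$snp_id)]
    snps <- snps$snp_id[order(snps$meta_p, pos)]
  }
  snps <- unique(as.character(snps))
  missing <- setdiff(snps, genotypes$snps$snp_id)
  if (length(missing))
    stop("SNP(s) missing from genotypes: ", paste(missing, collapse = ", "))
  remaining <- snps
  blocks <- list()
  independent <- character()
  while (length(remaining)) {
    rep_snp <- remaining[1]
    remaining <- remaining[-1]
    if (!length(remaining)) {
      independent <- c(independent, rep_snp)
      break
    }
    r2 <- vapply(remaining, function(s) {
      ld_r2(snp_dosage(genotypes, rep_snp), snp_dosage(genotypes, s))
    }, numeric(1))
    in_block <- !is.na(r2) & r2 > threshold
    if (any(in_block)) {
      blocks[[length(blocks) + 1L]] <- list(
        representative = rep_snp,
        members = remaining[in_block],
        r2 = unname(r2[in_block])
      )
      remaining <- remaining[!in_block]
    } else {
      independent <- c(independent, rep_snp)
    }
  }
  structure(list(blocks = blocks, independent = independent,
                 threshold = threshold),
            class = "ld_block_set")
}

#' @export
print.ld_block_set <- function(x, ...) {
  cat(sprintf("<ld_block_set> %d block(s), %d independent signal(s) (r2 > %g)\n",
              length(x$blocks), length(x$independent), x$threshold))
  for (b in x$blocks) {
    cat(sprintf("  block %s: %s\n", b$representative,
                paste(sprintf("%s (r2=%.3f)", b$members, b$r2),
                      collapse = ", ")))
  }
  if (length(x$independent))
    cat("  independent:", paste(x$independent, collapse = ", "), "\n")
  invisible(x)
}

#' Find LD proxies of a SNP
#'
#' SNPs within `window_bp` of the query whose dosage r2 with it is at least
#' `threshold` (inclusive, proxy-lookup convention), sorted by descending
#' r2. The query itself is excluded.
#'
#' @param query SNP id present in `genotypes` (error otherwise).
#' @param genotypes A `genotype_matrix`.
#' @param threshold r2 threshold (default 0.8, `>=`).
#' @param window_bp Search window around the query position (default 500 kb).
#' @return data.frame `snp_id`, `r2` (possibly empty).
#' @export
find_proxies <- function(query, genotypes, threshold = 0.8,
                         window_bp = 5e5) {
  qi <- match(query, genotypes$snps$snp_id)
  if (is.na(qi)) stop("query SNP not in genotypes: ", query)
  qpos <- genotypes$snps$position[qi]
  qchrom <- genotypes$snps$chrom[qi]
  cand <- genotypes$snps$snp_id[
    genotypes$snps$chrom == qchrom &
      abs(genotypes$snps$position - qpos) <= window_bp &
      genotypes$snps$snp_id != query
  ]
  if (!length(cand)) return(data.frame(snp_id = character(), r2 = numeric()))
  r2 <- vapply(cand, function(s) {
    ld_r2(snp_dosage(genotypes, query), snp_dosage(genotypes, s))
  }, numeric(1))
  keep <- !is.na(r2) & r2 >= threshold
  out <- data.frame(snp_id = cand[keep], r2 = unname(r2[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$r2), , drop = FALSE]
}

#' Cross-reference eSNPs (and their proxies) with a GWAS catalog
#'
#' For each eSNP, reports direct catalog hits (matching `snp_id`) and proxy
#' hits (catalog entries among the eSNP's LD proxies at `r2 >= threshold`),
#' each with trait, study and r2 (1 for direct hits), plus a summary count
#' of eSNPs with any hit. An empty catalog gives zero hits.
#'
#' @param esnps Character vector of significant SNP ids.
#' @param genotypes A `genotype_matrix` (for proxy lookup).
#' @param catalog data.frame with `snp_id`, `trait`, `study`.
#' @param threshold,window_bp Passed to [find_proxies()].
#' @return list of class `gwas_crossref`: `hits` (data.frame `esnp`,
#'   `hit_snp`, `type`, `r2`, `trait`, `study`), `n_esnps`,
#'   `n_with_hits`.
#' @export
gwas_crossref <- function(esnps, genotypes, catalog, threshold = 0.8,
                          window_bp = 5e5) {
  rows <- list()
  for (s in esnps) {
    direct <- catalog[catalog$snp_id == s, , drop = FALSE]
    if (nrow(direct)) {
      rows[[length(rows) + 1L]] <- data.frame(
        esnp = s, hit_snp = s, type = "direct", r2 = 1,
        trait = direct$trait, study = direct$study, stringsAsFactors = FALSE)
    }
    px <- find_proxies(s, genotypes, threshold = threshold,
                       window_bp = window_bp)
    hit <- merge(px, catalog, by = "snp_id")
    if (nrow(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        esnp = s, hit_snp = hit$snp_id, type = "proxy", r2 = hit$r2,
        trait = hit$trait, study = hit$study, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(esnp = character(), hit_snp = character(),
               type = character(), r2 = numeric(), trait = character(),
               study = character(), stringsAsFactors = FALSE)
  structure(list(hits = hits, n_esnps = length(esnps),
                 n_with_hits = length(unique(hits$esnp))),
            class = "gwas_crossref")
}

# Flatten an ld_block_set to a TSV-ready table.
ld_blocks_table <- function(bs) {
  rows <- list()
  for (i in seq_along(bs$blocks)) {
    b <- bs$blocks[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      block_id = i, representative = b$representative,
      member = c(b$representative, b$members),
      r2_to_representative = c(1, b$r2), stringsAsFactors = FALSE)
  }
  if (length(bs$independent)) {
    rows[[length(rows) + 1L]] <- data.frame(
      block_id = NA_integer_, representative = bs$independent,
      member = bs$independent, r2_to_representative = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(block_id = integer(), representative = character(),
                      member = character(), r2_to_representative = numeric()))
  }
  do.call(rbind, rows)
}
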
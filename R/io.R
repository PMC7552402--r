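# File-format interfaces. All coordinates are 1-based inclusive (SAM, GFF3,
# VCF conventions); delimited outputs are tab-separated with one header line.

#' Write gene models as GFF3
#'
#' Emits gene, transcript and exon features; retained introns are part of
#' the transcript's exon model (merged exon blocks), so each transcript's
#' exon rows directly describe its alignment blocks.
#'
#' @param genes A [gene_model()] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  lines <- "##gff-version 3"
  for (g in genes) {
    sp <- gene_span(g)
    lines <- c(lines, sprintf(
      "%s\tspliceflip\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chrom, sp[["start"]], sp[["end"]], g$strand, g$gene_id))
    for (v in g$variants) {
      tid <- paste0(g$gene_id, ".", v$variant_id)
      blocks <- variant_blocks(g, v$variant_id)
      lines <- c(lines, sprintf(
        "%s\tspliceflip\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;coding=%s",
        g$chrom, min(blocks$start), max(blocks$end), g$strand, tid,
        g$gene_id, tolower(v$coding)))
      lines <- c(lines, sprintf(
        "%s\tspliceflip\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        g$chrom, blocks$start, blocks$end, g$strand, tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads gene/transcript/exon features (via rtracklayer) and reconstructs
#' [gene_model()] objects. Transcript exon blocks are intersected across
#' variants to recover the gene's exon set; a transcript whose blocks merge
#' across a gene intron is recorded as retaining that intron. The coding
#' flag is taken from a `coding` attribute when present, else the variant
#' splicing all introns is coding.
#'
#' @param path GFF3 path.
#' @return Named list of [gene_model()] objects.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- df[df$type == "transcript" &
               vapply(df$Parent, function(p) gid %in% p, logical(1)), ]
    # exon union across transcripts defines the gene's exon set: exons are
    # the intersection of block boundaries (the fully spliced structure)
    all_blocks <- lapply(tx$ID, function(tid) {
      ex <- df[df$type == "exon" &
                 vapply(df$Parent, function(p) tid %in% p, logical(1)), ]
      ex[order(ex$start), c("start", "end")]
    })
    names(all_blocks) <- tx$ID
    # boundaries interior to any transcript: gene exons are the finest
    # partition: use the transcript with the most blocks as the exon set
    nb <- vapply(all_blocks, nrow, integer(1))
    exons <- all_blocks[[which.max(nb)]]
    rownames(exons) <- NULL
    introns <- data.frame(start = exons$end[-nrow(exons)] + 1L,
                          end = exons$start[-1] - 1L)
    variants <- list()
    for (k in seq_len(nrow(tx))) {
      blocks <- all_blocks[[tx$ID[k]]]
      retained <- which(vapply(seq_len(nrow(introns)), function(ii) {
        any(blocks$start <= introns$start[ii] & blocks$end >= introns$end[ii])
      }, logical(1)))
      coding <- if (!is.null(tx$coding)) {
        isTRUE(tx$coding[k] == "true")
      } else length(retained) == 0
      vid <- sub(paste0("^", gid, "\\."), "", tx$ID[k])
      variants[[length(variants) + 1L]] <-
        splice_variant(vid, coding = coding, retained_introns = retained)
    }
    out[[gid]] <- gene_model(gid, as.character(genes$seqnames[i]),
                             as.character(genes$strand[i]), exons, variants)
  }
  out
}

#' Write genotype dosages as TSV
#'
#' Columns: `snp_id`, `chrom`, `position`, `ref`, `alt`, `maf`, then one
#' column per sample holding the alt-allele dosage.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  out <- cbind(genotypes$snps[, c("snp_id", "chrom", "position", "ref",
                                  "alt", "maf")],
               as.data.frame(t(genotypes$dosages)))
  write_tsv(out, path)
}

#' Read genotype dosages from TSV
#' @param path Path written by [write_dosage_tsv()].
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  d <- read_tsv(path)
  meta_cols <- c("snp_id", "chrom", "position", "ref", "alt", "maf")
  samples <- setdiff(names(d), meta_cols)
  dosages <- t(as.matrix(d[, samples, with = FALSE]))
  colnames(dosages) <- d$snp_id
  rownames(dosages) <- samples
  structure(list(samples = samples,
                 snps = as.data.frame(d[, meta_cols, with = FALSE]),
                 dosages = dosages),
            class = "genotype_matrix")
}

#' Write genotypes as VCF with GT:DS fields
#'
#' Hard genotype calls are the rounded dosage; the DS field carries the
#' dosage itself.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path (`.vcf`).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(genotypes, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$samples), collapse = "\t")
  )
  gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1]
  rows <- vapply(seq_len(nrow(genotypes$snps)), function(i) {
    d <- genotypes$dosages[, i]
    cells <- sprintf("%s:%.3f", gt_of(d), d)
    paste(c(genotypes$snps$chrom[i], genotypes$snps$position[i],
            genotypes$snps$snp_id[i], genotypes$snps$ref[i],
            genotypes$snps$alt[i], ".", "PASS", ".", "GT:DS", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read alt-allele dosages from a VCF
#'
#' Uses the DS FORMAT field when present, else derives dosage from GT.
#'
#' @param path VCF path (plain text or gzipped).
#' @return A `genotype_matrix` (maf computed from the dosages).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(vapply(gt, function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    }, numeric(1)), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  dosages <- t(ds)
  snps <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                     position = as.integer(fix$POS), ref = fix$REF,
                     alt = fix$ALT, maf = NA_real_,
                     stringsAsFactors = FALSE)
  colnames(dosages) <- snps$snp_id
  snps$maf <- snp_maf(dosages)
  structure(list(samples = rownames(dosages), snps = snps,
                 dosages = dosages),
            class = "genotype_matrix")
}

#' Write / read an expression matrix as TSV
#'
#' Layout: first column `feature_id`, then one column per sample.
#'
#' @param mat samples x features matrix.
#' @param path Output path.
#' @return Invisibly, `path` (writer); samples x features matrix (reader).
#' @export
write_matrix_tsv <- function(mat, path) {
  out <- data.frame(feature_id = colnames(mat), t(mat),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- read_tsv(path)
  m <- t(as.matrix(d[, -1, with = FALSE]))
  colnames(m) <- d$feature_id
  m
}

#' Read a GWAS catalog extract
#'
#' TSV with columns `snp_id`, `trait`, `study`.
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
read_gwas_catalog <- function(path) {
  d <- as.data.frame(read_tsv(path))
  need <- c("snp_id", "trait", "study")
  if (!all(need %in% names(d)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  d[, need]
}
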
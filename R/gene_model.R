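#' Gene model with splice variants
#'
#' A `gene_model` describes one gene as an ordered set of exons plus a list of
#' splice variants. Each variant either splices an intron (its reads can span
#' the corresponding exon-exon junction) or retains it (the intron is part of
#' the variant's exon model and reads across it align contiguously). All
#' coordinates are 1-based inclusive reference coordinates, matching SAM and
#' GFF3 conventions; no half-open conversion is performed anywhere.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column data.frame (`start`, `end`), non-overlapping,
#'   sorted by start.
#' @param variants List of variants from [splice_variant()].
#' @return An object of class `gene_model` with derived `introns`
#'   (data.frame `index`, `start`, `end`).
#' @export
gene_model <- function(gene_id, chrom, strand, exons, variants) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (any(exons$end < exons$start)) stop_invalid("exon end before start")
  if (is.unsorted(exons$start, strictly = TRUE))
    stop_invalid("exons must be sorted by start")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop_invalid("exons must be non-overlapping")
  if (!strand %in% c("+", "-")) stop_invalid("strand must be '+' or '-'")
  n_introns <- nrow(exons) - 1L
  introns <- data.frame(
    index = seq_len(n_introns),
    start = exons$end[-nrow(exons)] + 1L,
    end   = exons$start[-1] - 1L
  )
  for (v in variants) {
    if (!all(v$retained_introns %in% introns$index))
      stop_invalid("variant ", v$variant_id, " retains unknown intron")
  }
  if (!any(vapply(variants, `[[`, logical(1), "coding")))
    stop_invalid("at least one variant must be coding")
  for (v in variants) {
    if (v$coding && length(v$retained_introns) > 0)
      stop_invalid("coding variant must splice all introns")
  }
  names(variants) <- vapply(variants, `[[`, character(1), "variant_id")
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, introns = introns, variants = variants),
    class = "gene_model"
  )
}

#' Splice variant of a gene
#'
#' @param variant_id Identifier.
#' @param coding Logical; coding variants splice every intron.
#' @param retained_introns Integer indices of retained introns (empty for the
#'   coding variant). Spliced junctions are the complement: the variant's
#'   spliced junctions and retained introns partition the gene's introns.
#' @return An object of class `splice_variant`.
#' @export
splice_variant <- function(variant_id, coding = FALSE,
                           retained_introns = integer()) {
  structure(
    list(variant_id = variant_id, coding = isTRUE(coding),
         retained_introns = as.integer(retained_introns)),
    class = "splice_variant"
  )
}

#' Introns spliced by a variant
#'
#' @param gene A [gene_model()].
#' @param variant_id Variant identifier.
#' @return Integer intron indices whose junctions the variant's reads can span.
#' @export
spliced_introns <- function(gene, variant_id) {
  v <- gene$variants[[variant_id]]
  if (is.null(v)) stop_invalid("unknown variant ", variant_id)
  setdiff(gene$introns$index, v$retained_introns)
}

#' Junction table of a gene
#'
#' One row per intron, keyed by (chrom, strand, intron_start, intron_end).
#'
#' @param gene A [gene_model()].
#' @return data.frame with columns `chrom`, `strand`, `intron_index`,
#'   `intron_start`, `intron_end`, `key`.
#' @export
gene_junctions <- function(gene) {
  data.frame(
    chrom = gene$chrom, strand = gene$strand,
    intron_index = gene$introns$index,
    intron_start = gene$introns$start, intron_end = gene$introns$end,
    key = junction_key(gene$chrom, gene$introns$start, gene$introns$end),
    stringsAsFactors = FALSE
  )
}

# Genomic span of the gene (first exon start to last exon end).
gene_span <- function(gene) {
  c(start = gene$exons$start[1], end = gene$exons$end[nrow(gene$exons)])
}

# Transcript structure of one variant: genomic blocks (exons, with retained
# introns merged in) and the spliced gaps between consecutive blocks.
variant_blocks <- function(gene, variant_id) {
  retained <- gene$variants[[variant_id]]$retained_introns
  starts <- gene$exons$start
  ends <- gene$exons$end
  blocks <- data.frame(start = starts[1], end = ends[1])
  for (i in seq_len(nrow(gene$exons) - 1L)) {
    if (i %in% retained) {
      # merge across the retained intron: block extends through next exon
      blocks$end[nrow(blocks)] <- ends[i + 1L]
    } else {
      blocks <- rbind(blocks, data.frame(start = starts[i + 1L],
                                         end = ends[i + 1L]))
    }
  }
  blocks$width <- blocks$end - blocks$start + 1L
  blocks
}

# Exon-model length of a variant (sum of block widths; retained introns count).
variant_length <- function(gene, variant_id) {
  sum(variant_blocks(gene, variant_id)$width)
}

#' Default three-exon gene model
#'
#' A three-exon gene with three splice variants: `V1` (coding, splices both
#' introns), `V2` (non-coding, retains the intron between exons 2 and 3) and
#' `V3` (non-coding, retains the intron between exons 1 and 2). A probe
#' targeting the exon2-exon3 junction therefore detects `V1` and `V3` only.
#'
#' @param gene_id,chrom Identifiers.
#' @param start Genomic start of exon 1.
#' @return A [gene_model()].
#' @export
default_gene_model <- function(gene_id = "GENE1", chrom = "chr22",
                               start = 23894000L) {
  e1 <- c(start, start + 299L)            # 300 bp
  i1 <- c(e1[2] + 1L, e1[2] + 500L)       # 500 bp
  e2 <- c(i1[2] + 1L, i1[2] + 200L)       # 200 bp
  i2 <- c(e2[2] + 1L, e2[2] + 800L)       # 800 bp
  e3 <- c(i2[2] + 1L, i2[2] + 400L)       # 400 bp
  gene_model(
    gene_id = gene_id, chrom = chrom, strand = "+",
    exons = data.frame(start = c(e1[1], e2[1], e3[1]),
                       end   = c(e1[2], e2[2], e3[2])),
    variants = list(
      splice_variant("V1", coding = TRUE),
      splice_variant("V2", retained_introns = 2L),
      splice_variant("V3", retained_introns = 1L)
    )
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exons, %d variants\n",
              x$gene_id, x$chrom, gene_span(x)[["start"]],
              gene_span(x)[["end"]], x$strand, nrow(x$exons),
              length(x$variants)))
  for (v in x$variants) {
    cat(sprintf("  %s %s retained introns: %s\n", v$variant_id,
                if (v$coding) "(coding)" else "(non-coding)",
                if (length(v$retained_introns)) {
                  paste(v$retained_introns, collapse = ",")
                } else "none"))
  }
  invisible(x)
}
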
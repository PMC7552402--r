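# Splice-junction quantification from CIGAR N operations.
#
# Coordinate conventions: SAM POS is 1-based; introns are stored 1-based
# inclusive (intron_start = first intronic base consumed by the N operation,
# intron_end = last). Reference-consuming operations: M, D, N, =, X.
# Non-consuming: I, S, H.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "=", "X")
REF_OPS <- c("M", "D", "N", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")

# Tokenize CIGAR strings; errors name the offending token. Tokenization is
# done once per distinct string (alignment streams repeat CIGARs heavily)
# and mapped back via `idx`.
parse_cigar_unique <- function(cigar) {
  u <- unique(cigar)
  m <- gregexpr("\\d+[A-Za-z=]?|[^0-9]", u, perl = TRUE)
  toks <- regmatches(u, m)
  flat <- unlist(toks, use.names = FALSE)
  ok <- grepl("^\\d+[MIDNSH=X]$", flat)
  if (!all(ok)) {
    bad <- flat[!ok][1]
    stop("malformed CIGAR: offending token '", bad, "'")
  }
  op <- substr(flat, nchar(flat), nchar(flat))
  len <- as.integer(substr(flat, 1L, nchar(flat) - 1L))
  list(
    n_unique = length(u), idx = match(cigar, u),
    tok = data.table::data.table(
      uread = rep(seq_along(u), lengths(toks)), op = op, len = len)
  )
}

# Per-op table with one row per (input read, op); for small inputs only.
parse_cigar <- function(cigar) {
  pc <- parse_cigar_unique(cigar)
  out <- pc$tok[data.table::data.table(read = seq_along(cigar),
                                       uread = pc$idx),
                on = "uread", allow.cartesian = TRUE]
  data.table::setorder(out, read)
  out[, .(read, op, len)]
}

# Vectorized per-unique reduction mapped back over all CIGARs.
cigar_sum_ops <- function(cigar, ops) {
  if (!length(cigar)) return(integer())
  pc <- parse_cigar_unique(cigar)
  pc$tok[, w := len * (op %in% ops)]
  per_u <- integer(pc$n_unique)
  agg <- pc$tok[, .(n = sum(w)), keyby = uread]
  per_u[agg$uread] <- as.integer(agg$n)
  per_u[pc$idx]
}

# Query length (SEQ length) per CIGAR.
cigar_query_length <- function(cigar) cigar_sum_ops(cigar, QUERY_OPS)

# Reference span (reference bases consumed) per CIGAR.
cigar_ref_span <- function(cigar) cigar_sum_ops(cigar, REF_OPS)

#' Extract splice junctions from alignment records
#'
#' Walks each CIGAR along the reference from the 1-based POS and emits one
#' junction per N operation: `intron_start` is the first reference base the
#' N consumes, `intron_end` the last. M, D, N, `=` and X consume reference;
#' I, S and H do not. Strand is unknown at this stage (assigned later from
#' the host gene).
#'
#' @param cigar Character vector of CIGAR strings (operations M, I, D, N, S,
#'   H, `=`, X). Malformed strings raise a parse error naming the offending
#'   token.
#' @param pos Integer vector of 1-based leftmost mapping positions (recycled
#'   if length 1).
#' @return data.table with one row per N operation: `read` (index into the
#'   input), `intron_start`, `intron_end`. Zero rows when no N operations
#'   are present.
#' @examples
#' extract_junctions("50M200N50M", pos = 100)  # intron (150, 349)
#' @export
extract_junctions <- function(cigar, pos = 1L) {
  if (!length(cigar)) {
    return(data.table::data.table(read = integer(),
                                  intron_start = integer(),
                                  intron_end = integer()))
  }
  pos <- as.integer(rep_len(pos, length(cigar)))
  if (any(is.na(pos) | pos < 1)) stop_invalid("POS must be >= 1")
  pc <- parse_cigar_unique(cigar)
  tok <- pc$tok
  tok[, ref := len * (op %in% REF_OPS)]
  # reference offset before each op within its (unique) CIGAR
  tok[, before := cumsum(ref) - ref, by = uread]
  ns <- tok[op == "N", .(uread, before, len)]
  reads <- data.table::data.table(read = seq_along(cigar), uread = pc$idx,
                                  pos = pos)
  jx <- ns[reads, on = "uread", allow.cartesian = TRUE, nomatch = NULL]
  data.table::setorder(jx, read, before)
  data.table::data.table(
    read = jx$read,
    intron_start = jx$pos + as.integer(jx$before),
    intron_end = jx$pos + as.integer(jx$before) + jx$len - 1L
  )
}

#' Count splice junctions per sample and annotate to host genes
#'
#' Each (sample, junction) cell is the number of N operations with that
#' (chrom, strand, intron_start, intron_end) key in the sample; a read with
#' k N operations contributes 1 to each of k junctions. A junction is
#' assigned to the gene whose span fully contains the intron; if several
#' genes qualify, the gene with the smallest span wins and the ambiguity is
#' reported via `message()`. Junctions matching no gene keep strand
#' `"unknown"` and `gene_id` NA (they are dropped at normalization). Strand
#' is taken from the host gene; reads are treated as unstranded.
#'
#' @param reads data.table of alignments (`sample_id`, `rname`, `pos`,
#'   `cigar`, ...) from [render_reads()]`$reads` or [read_sam()], or a
#'   `read_set`.
#' @param annotation A [gene_model()] or list of them.
#' @param min_mapq Minimum mapping quality; records below are ignored
#'   entirely (default 0 = no filter).
#' @return Object of class `junction_counts`: list with `junctions`
#'   (data.frame `chrom`, `strand`, `intron_start`, `intron_end`, `gene_id`,
#'   `key`), `counts` (samples x junctions integer matrix),
#'   `library_sizes` (mapped reads per sample) and `gene_totals`
#'   (samples x genes matrix of reads overlapping each gene span,
#'   used for gene-wise normalization).
#' @export
count_junctions <- function(reads, annotation, min_mapq = 0) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  reads <- data.table::as.data.table(reads)
  if (inherits(annotation, "gene_model")) annotation <- list(annotation)
  names(annotation) <-
    vapply(annotation, `[[`, character(1), "gene_id")
  if (min_mapq > 0 && "mapq" %in% names(reads))
    reads <- reads[mapq >= min_mapq]
  samples <- sort(unique(reads$sample_id))

  jx <- extract_junctions(reads$cigar, reads$pos)
  jx[, `:=`(sample_id = reads$sample_id[read],
            chrom = reads$rname[read])]
  jtab <- unique(jx[, .(chrom, intron_start, intron_end)])
  data.table::setorder(jtab, chrom, intron_start, intron_end)

  # gene assignment: smallest gene span fully containing the intron
  genes <- data.table::rbindlist(lapply(annotation, function(g) {
    sp <- gene_span(g)
    data.table::data.table(gene_id = g$gene_id, chrom = g$chrom,
                           start = sp[["start"]], end = sp[["end"]],
                           strand = g$strand,
                           span = sp[["end"]] - sp[["start"]] + 1L)
  }))
  jtab[, `:=`(gene_id = NA_character_, strand = "unknown")]
  if (nrow(jtab)) {
    for (i in seq_len(nrow(jtab))) {
      hits <- genes[chrom == jtab$chrom[i] & start <= jtab$intron_start[i] &
                      end >= jtab$intron_end[i]]
      if (nrow(hits) > 1) {
        hits <- hits[order(span)]
        message(sprintf(
          "junction %s assigned to %s (smallest span) among: %s",
          junction_key(jtab$chrom[i], jtab$intron_start[i],
                       jtab$intron_end[i]),
          hits$gene_id[1], paste(hits$gene_id, collapse = ", ")))
      }
      if (nrow(hits)) {
        jtab$gene_id[i] <- hits$gene_id[1]
        jtab$strand[i] <- hits$strand[1]
      }
    }
  }
  jtab[, key := junction_key(chrom, intron_start, intron_end)]

  counts <- matrix(0L, length(samples), nrow(jtab),
                   dimnames = list(samples, jtab$key))
  if (nrow(jx)) {
    jx[, key := junction_key(chrom, intron_start, intron_end)]
    agg <- jx[, .(n = .N), by = .(sample_id, key)]
    counts[cbind(match(agg$sample_id, samples),
                 match(agg$key, jtab$key))] <- as.integer(agg$n)
  }

  library_sizes <- setNames(integer(length(samples)), samples)
  ls <- reads[, .(n = .N), by = sample_id]
  library_sizes[ls$sample_id] <- as.integer(ls$n)

  # per-gene totals: reads whose reference span overlaps the gene span
  gene_totals <- matrix(0L, length(samples), nrow(genes),
                        dimnames = list(samples, genes$gene_id))
  if (nrow(reads)) {
    read_end <- reads$pos + cigar_ref_span(reads$cigar) - 1L
    for (gi in seq_len(nrow(genes))) {
      sel <- reads$rname == genes$chrom[gi] &
        reads$pos <= genes$end[gi] & read_end >= genes$start[gi]
      tt <- reads[sel, .(n = .N), by = sample_id]
      gene_totals[match(tt$sample_id, samples), gi] <- as.integer(tt$n)
    }
  }

  structure(list(
    junctions = as.data.frame(jtab[, .(chrom, strand, intron_start,
                                       intron_end, gene_id, key)]),
    counts = counts, library_sizes = library_sizes,
    gene_totals = gene_totals
  ), class = "junction_counts")
}

#' Normalize junction counts for library size and gene-wise abundance
#'
#' Two-step normalization. Library size: counts are divided by
#' `L_i / median(L)` (median-of-ratios on total mapped reads), which removes
#' a pure library-size factor exactly. Gene-wise transcript abundance: the
#' library-size-scaled count is divided by `max(g_i, eps)` where `g_i` is
#' the sample's library-size-scaled total reads over the junction's host
#' gene relative to the across-sample median of that gene total. The result
#' is interpretable as relative splice usage: multiplying all of one gene's
#' reads in one sample by a constant leaves that gene's normalized junction
#' values unchanged. Junctions without a host gene are dropped with a
#' warning; genes with zero reads in all samples yield zeros with a warning.
#'
#' @param jc A `junction_counts` object from [count_junctions()].
#' @param eps Guard against division by zero in the gene factor.
#' @return Object of class `junction_norm`: list with `junctions`, `values`
#'   (samples x junctions numeric matrix), `library_sizes`.
#' @export
normalize_junction_counts <- function(jc, eps = 1e-8) {
  keep <- !is.na(jc$junctions$gene_id)
  if (any(!keep)) {
    warning(sum(!keep), " junction(s) without host gene dropped from ",
            "normalization")
  }
  junctions <- jc$junctions[keep, , drop = FALSE]
  counts <- jc$counts[, keep, drop = FALSE]
  L <- jc$library_sizes
  with_reads <- L > 0
  lib_factor <- ifelse(with_reads, L / median(L[with_reads]), 1)
  scaled <- sweep(counts, 1, lib_factor, "/")

  gene_scaled <- sweep(jc$gene_totals, 1, lib_factor, "/")
  gene_median <- apply(gene_scaled, 2, median)
  dead <- gene_median <= 0
  if (any(dead[unique(junctions$gene_id)])) {
    warning("gene(s) with zero reads in all samples: ",
            paste(colnames(gene_scaled)[dead], collapse = ", "),
            "; their junctions are emitted as zero")
  }
  gene_median[dead] <- 1
  g <- sweep(gene_scaled, 2, gene_median, "/")  # samples x genes

  values <- scaled
  for (j in seq_len(ncol(values))) {
    gid <- junctions$gene_id[j]
    values[, j] <- scaled[, j] / pmax(g[, gid], eps)
    if (dead[gid]) values[, j] <- 0
  }
  structure(list(junctions = junctions, values = values,
                 library_sizes = L),
            class = "junction_norm")
}

#' Write junction count or normalized matrices as TSV
#'
#' Columns: `chrom`, `strand`, `intron_start`, `intron_end`, `gene_id`,
#' then one column per sample.
#'
#' @param x A `junction_counts` or `junction_norm` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_junction_tsv <- function(x, path) {
  mat <- if (inherits(x, "junction_counts")) x$counts else x$values
  out <- cbind(
    x$junctions[, c("chrom", "strand", "intron_start", "intron_end",
                    "gene_id")],
    as.data.frame(t(mat))
  )
  write_tsv(out, path)
}
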
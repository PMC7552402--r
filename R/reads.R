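#' Render single-end split reads from variant abundances
#'
#' Places error-free single-end reads uniformly along each splice variant's
#' transcript and maps them back to reference coordinates. The number of
#' reads from variant v in sample i is Poisson with mean
#' `abundance[i, v] * depth_factor * L_v / 1000` (fragment mass proportional
#' to transcript length), so sequencing noise is Poisson. Reads that overlap
#' a spliced junction carry an N operation whose reference span equals the
#' intron; reads within retained introns are contiguous M.
#'
#' @param abundances samples x variants matrix
#'   (see [simulate_variant_abundances()]).
#' @param gene A [gene_model()].
#' @param read_length Read length in bases (> 0). Transcripts shorter than
#'   the read length yield reads truncated to the transcript.
#' @param depth_factor Expected reads per abundance unit per transcript kb.
#' @param seed Integer seed.
#' @return Object of class `read_set`: list with `reads` (data.table:
#'   `sample_id`, `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`) sorted by
#'   sample then position, and `sq` (data.frame `sn`, `ln`) for the SAM
#'   header.
#' @export
render_reads <- function(abundances, gene, read_length = 75L,
                         depth_factor = 50, seed = 1L) {
  if (!is.numeric(read_length) || read_length <= 0)
    stop_invalid("read_length must be > 0")
  read_length <- as.integer(read_length)
  set.seed(as.integer(seed))
  samples <- rownames(abundances)
  vn <- colnames(abundances)
  pieces <- vector("list", length(vn))

  for (k in seq_along(vn)) {
    v <- vn[k]
    blocks <- variant_blocks(gene, v)
    L <- sum(blocks$width)
    rl <- min(read_length, L)
    n_starts <- L - rl + 1L
    mean_reads <- abundances[, v] * depth_factor * L / 1000
    n_reads <- rpois(length(samples), mean_reads)
    total <- sum(n_reads)
    if (total == 0) next
    sample_idx <- rep(seq_along(samples), n_reads)
    s <- sample.int(n_starts, total, replace = TRUE)   # transcript start
    e <- s + rl - 1L
    cum <- cumsum(blocks$width)
    i1 <- findInterval(s - 1L, cum) + 1L
    i2 <- findInterval(e - 1L, cum) + 1L
    pos <- blocks$start[i1] + (s - 1L) - c(0L, cum)[i1]
    # build CIGARs per (i1, i2) combination; few combinations per gene
    cigar <- character(total)
    gaps <- if (nrow(blocks) > 1) {
      blocks$start[-1] - blocks$end[-nrow(blocks)] - 1L
    } else integer()
    for (a in unique(i1)) {
      for (b in unique(i2[i1 == a])) {
        sel <- i1 == a & i2 == b
        if (a == b) {
          cigar[sel] <- sprintf("%dM", rl)
        } else {
          # pattern M (N M)* N M: first and last M vary per read, middle
          # N/M pairs are fixed for a given block pair
          first_m <- cum[a] - s[sel] + 1L
          last_m <- e[sel] - cum[b - 1L]
          mid <- if (b - a > 1) {
            paste0(sprintf("%dN%dM", gaps[a:(b - 2L)],
                           blocks$width[(a + 1L):(b - 1L)]),
                   collapse = "")
          } else ""
          cigar[sel] <- sprintf("%dM%s%dN%dM", first_m, mid,
                                gaps[b - 1L], last_m)
        }
      }
    }
    pieces[[k]] <- data.table::data.table(
      sample_id = samples[sample_idx], variant = v,
      pos = as.integer(pos), cigar = cigar
    )
  }
  reads <- data.table::rbindlist(pieces)
  if (nrow(reads) == 0) {
    reads <- data.table::data.table(
      sample_id = character(), qname = character(), flag = integer(),
      rname = character(), pos = integer(), mapq = integer(),
      cigar = character()
    )
  } else {
    data.table::setorder(reads, sample_id, pos, cigar)
    reads[, qname := sprintf("%s_%s_r%07d", sample_id, variant,
                             seq_len(.N))]
    reads[, `:=`(flag = 0L, rname = gene$chrom, mapq = 60L, variant = NULL)]
    data.table::setcolorder(reads, c("sample_id", "qname", "flag", "rname",
                                     "pos", "mapq", "cigar"))
  }
  span <- gene_span(gene)
  structure(list(
    reads = reads,
    sq = data.frame(sn = gene$chrom, ln = span[["end"]] + 1000L,
                    stringsAsFactors = FALSE)
  ), class = "read_set")
}

#' Write a read set as per-sample SAM files
#'
#' Emits valid SAM with `@HD` and `@SQ` header lines, 1-based POS and CIGARs
#' using M/N operations only. SEQ is written as a run of `A`s of the read's
#' query length; QUAL is `*`.
#'
#' @param read_set A `read_set` from [render_reads()].
#' @param dir Output directory; one `<sample>.sam` per sample.
#' @param samples Optional sample subset; defaults to all samples present
#'   (samples with zero reads still get a header-only file if listed here).
#' @return Invisibly, the paths written.
#' @export
write_sam <- function(read_set, dir, samples = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reads <- read_set$reads
  samples <- samples %||% sort(unique(reads$sample_id))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", read_set$sq$sn, read_set$sq$ln))
  paths <- character(length(samples))
  qlen <- cigar_query_length(reads$cigar)
  for (i in seq_along(samples)) {
    s <- samples[i]
    sel <- reads$sample_id == s
    lines <- character()
    if (any(sel)) {
      r <- reads[sel]
      lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                       r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
                       strrep("A", qlen[sel]))
    }
    paths[i] <- file.path(dir, paste0(s, ".sam"))
    writeLines(c(header, lines), paths[i])
  }
  invisible(paths)
}

#' Read SAM files into an alignment table
#'
#' Parses plain-text SAM (header lines skipped), keeping the fields the
#' junction quantifier needs. Unmapped records (FLAG bit 0x4 or `*` CIGAR)
#' are dropped.
#'
#' @param paths SAM file paths; the sample identifier is the file name
#'   without extension unless `sample_ids` is given.
#' @param sample_ids Optional sample identifiers matching `paths`.
#' @return data.table with columns `sample_id`, `qname`, `flag`, `rname`,
#'   `pos`, `mapq`, `cigar`.
#' @export
read_sam <- function(paths, sample_ids = NULL) {
  sample_ids <- sample_ids %||%
    tools::file_path_sans_ext(basename(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    lines <- readLines(paths[i])
    lines <- lines[!startsWith(lines, "@")]
    if (!length(lines)) {
      out[[i]] <- data.table::data.table(
        sample_id = character(), qname = character(), flag = integer(),
        rname = character(), pos = integer(), mapq = integer(),
        cigar = character())
      next
    }
    f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:6)
    dt <- data.table::data.table(
      sample_id = sample_ids[i], qname = f[[1]],
      flag = as.integer(f[[2]]), rname = f[[3]],
      pos = as.integer(f[[4]]), mapq = as.integer(f[[5]]), cigar = f[[6]]
    )
    out[[i]] <- dt[cigar != "*" & bitwAnd(flag, 4L) == 0L]
  }
  data.table::rbindlist(out)
}
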
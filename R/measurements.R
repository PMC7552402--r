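#' Render probe-style and total (FPKM) expression measurements
#'
#' Microarray-probe mode: the probe targets one exon-exon junction and
#' detects only variants that splice it;
#' `probe_log2 = log2(sum of detected abundances) + Normal(0, noise_sd_probe)`.
#' RNA-seq mode: per-variant expected fragments are
#' `abundance * depth_factor * L_v / 1000` (fragment mass proportional to
#' exon-model length `L_v`, retained introns included); FPKM of a variant is
#' `fragments / ((L_v/1000) * (library_size/1e6))` and `total_fpkm` is the
#' sum over variants, so doubling every abundance together with the library
#' size leaves total FPKM unchanged.
#'
#' @param abundances samples x variants matrix.
#' @param gene A [gene_model()].
#' @param probe_junction Intron index (1-based) or junction key string of
#'   the junction the probe targets; must be a junction of `gene`.
#' @param noise_sd_probe SD of log2-scale probe noise.
#' @param seed Integer seed.
#' @param library_sizes Optional per-sample library sizes (total mapped
#'   fragments in the whole library). The default is a constant 2e7 per
#'   sample: the gene under study contributes a negligible share of a real
#'   library, so its own abundance must not feed back into the
#'   per-million denominator.
#' @param depth_factor Expected fragments per abundance unit per kb.
#' @return list of class `measurement_set` (partial: no junction counts)
#'   with `probe_log2`, `total_fpkm`, `library_sizes`, `probe_junction`
#'   (key string), `detected_variants`.
#' @export
render_measurements <- function(abundances, gene, probe_junction,
                                noise_sd_probe = 0.1, seed = 1L,
                                library_sizes = NULL, depth_factor = 50) {
  set.seed(as.integer(seed))
  jx <- gene_junctions(gene)
  if (is.character(probe_junction)) {
    ji <- match(probe_junction, jx$key)
  } else {
    ji <- match(as.integer(probe_junction), jx$intron_index)
  }
  if (is.na(ji)) stop_invalid("probe_junction is not a junction of ",
                              gene$gene_id)
  detected <- names(gene$variants)[vapply(names(gene$variants), function(v) {
    jx$intron_index[ji] %in% spliced_introns(gene, v)
  }, logical(1))]
  vn <- colnames(abundances)
  lens <- vapply(vn, function(v) variant_length(gene, v), numeric(1))
  probe_sum <- rowSums(abundances[, detected, drop = FALSE])
  probe_log2 <- log2(probe_sum) +
    rnorm(nrow(abundances), 0, noise_sd_probe)
  frags <- sweep(abundances, 2, depth_factor * lens / 1000, "*")
  lib <- rep_len(library_sizes %||% 2e7, nrow(abundances))
  fpkm <- sweep(frags, 2, lens / 1000, "/")
  fpkm <- sweep(fpkm, 1, lib / 1e6, "/")
  structure(list(
    probe_log2 = setNames(probe_log2, rownames(abundances)),
    total_fpkm = setNames(rowSums(fpkm), rownames(abundances)),
    library_sizes = setNames(lib, rownames(abundances)),
    probe_junction = jx$key[ji], detected_variants = detected
  ), class = "measurement_set")
}

#' Simulate a complete measurement set for one gene
#'
#' Convenience wrapper over the full generative path: draws variant
#' abundances, renders the probe-style and total-FPKM measurements, renders
#' split reads, counts junctions from their CIGAR N operations and
#' normalizes them. This is the per-sample input the direction-of-effect
#' reconciliation consumes.
#'
#' @param genotypes,covariates,gene,spec,seed As in
#'   [simulate_variant_abundances()].
#' @param probe_junction Junction targeted by the probe (intron index or
#'   key); default 2 (the exon2-exon3 junction of the default gene).
#' @param read_length,depth_factor Passed to [render_reads()].
#' @param noise_sd_probe Probe noise SD.
#' @return `measurement_set` with `probe_log2`, `total_fpkm`,
#'   `junction_counts` (`junction_counts` object), `junction_norm`
#'   (samples x junctions matrix of normalized split reads),
#'   `library_sizes`, `abundances`.
#' @export
simulate_measurement_set <- function(genotypes, covariates, gene, spec,
                                     seed = 1L, probe_junction = 2L,
                                     read_length = 75L, depth_factor = 10,
                                     noise_sd_probe = 0.1) {
  ab <- simulate_variant_abundances(genotypes, covariates, gene, spec,
                                    seed = seed)
  ms <- render_measurements(ab, gene, probe_junction,
                            noise_sd_probe = noise_sd_probe,
                            seed = seed + 1L)
  rs <- render_reads(ab, gene, read_length = read_length,
                     depth_factor = depth_factor, seed = seed + 2L)
  jc <- count_junctions(rs, gene)
  jn <- suppressWarnings(normalize_junction_counts(jc))
  # align junction matrix rows to the full sample set (zero-read samples)
  values <- matrix(0, nrow(ab), nrow(jn$junctions),
                   dimnames = list(rownames(ab), colnames(jn$values)))
  values[rownames(jn$values), ] <- jn$values
  ms$junction_counts <- jc
  ms$junction_norm <- values
  ms$abundances <- ab
  ms
}
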
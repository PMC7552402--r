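# End-to-end orchestrator: simulate -> quantify -> prep/diffexp -> eqtl ->
# spliceqtl -> ldblocks -> gwas-xref -> reconcile.

#' Default pipeline configuration
#'
#' The default scenario: a three-cohort case/control cohort, genotypes with
#' three planted LD blocks plus independent SNPs and a focal SNP carrying
#' the direction-flip effect, the three-variant gene model, and the default
#' flip effect specification.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return Nested configuration list (YAML-compatible).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_samples = 240L, n_copd = 120L, n_cohorts = 3L),
    genotypes = list(
      blocks = list(
        list(n_snps = 4L, maf = 0.3, within_block_r2 = 0.95),
        list(n_snps = 3L, maf = 0.2, within_block_r2 = 0.95),
        list(n_snps = 2L, maf = 0.4, within_block_r2 = 0.95)
      ),
      independent_mafs = c(0.2, 0.4),
      focal_snp = list(id = "rs_flip", maf = 0.3),
      chrom = "chr22", start_pos = 23400000L, spacing_bp = 40000L
    ),
    gene = list(gene_id = "GENE1", chrom = "chr22", start = 23894000L),
    effects = list(kind = "flip", noise_sd = 0.25,
                   disease_shift_coding = 0.3),
    reads = list(read_length = 75L, depth_factor = 10),
    probe = list(junction = 2L, noise_sd = 0.1),
    qtl = list(window_bp = 1e6, maf = 0.05, alpha = 0.05),
    ld = list(threshold = 0.8, proxy_window_bp = 5e5),
    catalog = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Checks structure and value ranges before any stage runs; raises an
#' invalid-parameter error naming the offending field.
#'
#' @param config Configuration list (see [default_config()]) or a YAML path.
#' @return The validated config (with the YAML loaded, if a path was given).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(cond, what) if (!isTRUE(cond))
    stop_invalid("config: ", what)
  need(is.list(config), "must be a list")
  need(is_count(config$seed %||% NA), "seed must be an integer")
  need(is_count(config$cohort$n_samples) && config$cohort$n_samples >= 2,
       "cohort.n_samples must be a count >= 2")
  need(is_count(config$cohort$n_copd) &&
         config$cohort$n_copd <= config$cohort$n_samples,
       "cohort.n_copd must be a count <= n_samples")
  for (b in config$genotypes$blocks) {
    b <- as.list(b)
    need(is.numeric(b$maf) && b$maf > 0 && b$maf <= 0.5,
         "block maf must be in (0, 0.5]")
    need(is.numeric(b$within_block_r2) && b$within_block_r2 >= 0 &&
           b$within_block_r2 <= 1, "within_block_r2 must be in [0,1]")
  }
  need(!is.null(config$genotypes$focal_snp$id), "genotypes.focal_snp.id")
  need(is.numeric(config$reads$read_length) && config$reads$read_length > 0,
       "reads.read_length must be > 0")
  need(config$effects$kind %in% c("flip", "null"),
       "effects.kind must be 'flip' or 'null'")
  need(is.numeric(config$qtl$window_bp) && config$qtl$window_bp > 0,
       "qtl.window_bp must be > 0")
  config
}

# Small synthetic GWAS catalog used when the config supplies none; its SNP
# ids deliberately do not overlap the simulated genotypes.
default_gwas_catalog <- function() {
  data.frame(
    snp_id = c("rs_gwas_1", "rs_gwas_2", "rs_gwas_3"),
    trait = c("COPD", "FEV1", "FEV1/FVC"),
    study = c("synthetic_gwas_a", "synthetic_gwas_b", "synthetic_gwas_c"),
    stringsAsFactors = FALSE
  )
}

#' Run the full pipeline
#'
#' Executes simulate, quantify, prep, diffexp, eqtl, spliceqtl, ldblocks,
#' gwas-xref and reconcile in order, writing every stage artifact as TSV
#' (plus SAM, GFF3, VCF) under `out_dir` together with a `manifest.json`
#' recording the configuration and outputs. Re-running with the same
#' configuration reproduces byte-identical delimited outputs. A stage
#' failure aborts with the stage name after writing a partial manifest.
#'
#' @param config Configuration list or YAML path (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`genotypes`, `covariates`, `gene`, `measurements`, `labels`,
#'   `diffexp`, `eqtl`, `spliceqtl`, `ld_blocks`, `gwas`, `direction`).
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(config = config)
  done <- character()
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, fun) {
    say("[", name, "]")
    res <- tryCatch(fun(), error = function(e) {
      manifest <- list(config = config, completed_stages = done,
                       failed_stage = name,
                       package_version = as.character(
                         utils::packageVersion("spliceflip")))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    done <<- c(done, name)
    res
  }
  seed <- config$seed

  state <- c(state, stage("simulate", function() {
    gspec <- config$genotypes
    ind_mafs <- c(gspec$independent_mafs, gspec$focal_snp$maf)
    ind_ids <- c(sprintf("rs_i%d", seq_along(gspec$independent_mafs)),
                 gspec$focal_snp$id)
    genotypes <- simulate_genotypes(
      n_samples = config$cohort$n_samples, block_spec = gspec$blocks,
      n_independent = length(ind_mafs), seed = seed,
      chrom = gspec$chrom, start_pos = gspec$start_pos,
      spacing_bp = gspec$spacing_bp,
      independent_mafs = ind_mafs, independent_ids = ind_ids)
    covariates <- simulate_cohort(config$cohort$n_samples,
                                  config$cohort$n_copd, seed = seed + 1L,
                                  n_cohorts = config$cohort$n_cohorts)
    gene <- default_gene_model(config$gene$gene_id, config$gene$chrom,
                               as.integer(config$gene$start))
    spec <- if (config$effects$kind == "flip") {
      default_flip_spec(gspec$focal_snp$id,
                        disease_shift_coding =
                          config$effects$disease_shift_coding,
                        noise_sd = config$effects$noise_sd)
    } else {
      null_effect_spec(noise_sd = config$effects$noise_sd)
    }
    ab <- simulate_variant_abundances(genotypes, covariates, gene, spec,
                                      seed = seed + 2L)
    ms <- render_measurements(ab, gene, config$probe$junction,
                              noise_sd_probe = config$probe$noise_sd,
                              seed = seed + 3L,
                              depth_factor = config$reads$depth_factor)
    rs <- render_reads(ab, gene, read_length = config$reads$read_length,
                       depth_factor = config$reads$depth_factor,
                       seed = seed + 4L)
    write_tsv(covariates, file.path(out_dir, "covariates.tsv"))
    write_dosage_tsv(genotypes, file.path(out_dir, "dosages.tsv"))
    write_vcf(genotypes, file.path(out_dir, "genotypes.vcf"))
    write_gff3(gene, file.path(out_dir, "gene_model.gff3"))
    write_matrix_tsv(ab, file.path(out_dir, "abundances.tsv"))
    write_matrix_tsv(cbind(probe_log2 = ms$probe_log2),
                     file.path(out_dir, "probe_log2.tsv"))
    write_matrix_tsv(cbind(total_fpkm = ms$total_fpkm),
                     file.path(out_dir, "total_fpkm.tsv"))
    write_sam(rs, file.path(out_dir, "sam"), samples = covariates$sample_id)
    list(genotypes = genotypes, covariates = covariates, gene = gene,
         effect_spec = spec, abundances = ab, measurements = ms,
         reads = rs)
  }))

  state <- c(state, stage("quantify", function() {
    paths <- file.path(out_dir, "sam",
                       paste0(state$covariates$sample_id, ".sam"))
    reads <- read_sam(paths, sample_ids = state$covariates$sample_id)
    jc <- count_junctions(reads, state$gene)
    jn <- suppressWarnings(normalize_junction_counts(jc))
    write_junction_tsv(jc, file.path(out_dir, "junction_counts.tsv"))
    write_junction_tsv(jn, file.path(out_dir, "junction_norm.tsv"))
    write_tsv(data.frame(sample_id = names(jc$library_sizes),
                         library_size = unname(jc$library_sizes)),
              file.path(out_dir, "library_sizes.tsv"))
    jn_full <- matrix(0, nrow(state$abundances), ncol(jn$values),
                      dimnames = list(rownames(state$abundances),
                                      colnames(jn$values)))
    jn_full[rownames(jn$values), ] <- jn$values
    list(junction_counts = jc, junction_norm = jn_full)
  }))

  state <- c(state, stage("prep", function() {
    labels <- classify_cohort(state$covariates)
    expr <- cbind(probe_log2 = state$measurements$probe_log2,
                  total_log2fpkm = log2(state$measurements$total_fpkm))
    inc <- labels$label != "excluded"
    adjusted <- adjust_expression(expr[inc, , drop = FALSE],
                                  state$covariates[inc, ])
    write_tsv(labels, file.path(out_dir, "cohort_labels.tsv"))
    write_matrix_tsv(adjusted, file.path(out_dir, "adjusted_expression.tsv"))
    list(labels = labels, adjusted = adjusted, included = inc)
  }))

  state <- c(state, stage("diffexp", function() {
    inc <- state$included
    de <- compare_groups(state$adjusted, state$labels[inc, ],
                         covariates = state$covariates[inc, ],
                         by_gold_stage = TRUE)
    corr <- correlate_lung_function(state$adjusted,
                                    state$covariates[inc, ],
                                    state$labels[inc, ])
    write_tsv(de, file.path(out_dir, "diffexp.tsv"))
    write_tsv(corr, file.path(out_dir, "lung_function_correlations.tsv"))
    list(diffexp = de, correlations = corr)
  }))

  state <- c(state, stage("eqtl", function() {
    jx <- gene_junctions(state$gene)
    probe_key <- state$measurements$probe_junction
    anchor_pos <- jx$intron_start[match(probe_key, jx$key)]
    expr <- cbind(probe = state$measurements$probe_log2,
                  total = log2(state$measurements$total_fpkm))
    anchors <- data.frame(
      feature_id = c("probe", "total"), chrom = state$gene$chrom,
      position = c(anchor_pos, anchor_pos))
    scan <- qtl_scan(expr, state$genotypes, state$covariates, anchors,
                     window_bp = config$qtl$window_bp,
                     maf = config$qtl$maf, alpha = config$qtl$alpha,
                     smoking_coding = "current_ex")
    write_tsv(scan$meta, file.path(out_dir, "eqtl_meta.tsv"))
    write_tsv(scan$per_cohort, file.path(out_dir, "eqtl_per_cohort.tsv"))
    list(eqtl = scan)
  }))

  state <- c(state, stage("spliceqtl", function() {
    jn <- state$junction_norm
    jx <- state$junction_counts$junctions
    anchors <- data.frame(feature_id = colnames(jn),
                          chrom = jx$chrom[match(colnames(jn), jx$key)],
                          position = jx$intron_start[match(colnames(jn),
                                                           jx$key)])
    scan <- qtl_scan(jn, state$genotypes, state$covariates, anchors,
                     window_bp = config$qtl$window_bp,
                     maf = config$qtl$maf, alpha = config$qtl$alpha,
                     smoking_coding = "current")
    write_tsv(scan$meta, file.path(out_dir, "spliceqtl_meta.tsv"))
    list(spliceqtl = scan)
  }))

  state <- c(state, stage("ldblocks", function() {
    sig <- state$eqtl$meta[state$eqtl$meta$significant %in% TRUE, ]
    sig <- sig[!duplicated(sig$snp_id), ]
    bs <- if (nrow(sig)) {
      cluster_ld_blocks(sig[, c("snp_id", "meta_p")], state$genotypes,
                        threshold = config$ld$threshold)
    } else {
      structure(list(blocks = list(), independent = character(),
                     threshold = config$ld$threshold),
                class = "ld_block_set")
    }
    write_tsv(ld_blocks_table(bs), file.path(out_dir, "ld_blocks.tsv"))
    list(ld_blocks = bs, significant_esnps = sig$snp_id)
  }))

  state <- c(state, stage("gwas_xref", function() {
    catalog <- if (is.null(config$catalog)) default_gwas_catalog()
               else read_gwas_catalog(config$catalog)
    xr <- gwas_crossref(state$significant_esnps, state$genotypes, catalog,
                        threshold = config$ld$threshold,
                        window_bp = config$ld$proxy_window_bp)
    write_tsv(xr$hits, file.path(out_dir, "gwas_xref.tsv"))
    list(gwas = xr)
  }))

  state <- c(state, stage("reconcile", function() {
    ms <- state$measurements
    ms$junction_norm <- state$junction_norm
    dr <- direction_profile(config$genotypes$focal_snp$id, ms,
                            state$genotypes, state$covariates,
                            alpha = config$qtl$alpha, maf = config$qtl$maf)
    write_tsv(direction_report_table(dr),
              file.path(out_dir, "direction_report.tsv"))
    digest <- c(
      sprintf("focal SNP: %s", dr$snp_id),
      sprintf("flip (probe vs total, gate p < %g): %s", dr$alpha,
              ifelse(is.na(dr$flip_flag), "undetermined", dr$flip_flag)),
      sprintf("%-24s beta %+.4f p %.3g high %s", dr$modes$mode,
              dr$modes$beta, dr$modes$p_value,
              dr$modes$genotype_high_expression),
      sprintf("significant eSNPs: %d", length(state$significant_esnps)),
      sprintf("LD blocks: %d; independent signals: %d",
              length(state$ld_blocks$blocks),
              length(state$ld_blocks$independent)),
      sprintf("GWAS catalog hits: %d of %d eSNPs",
              state$gwas$n_with_hits, state$gwas$n_esnps)
    )
    writeLines(digest, file.path(out_dir, "summary.txt"))
    list(direction = dr)
  }))

  manifest <- list(
    config = config, completed_stages = done,
    package_version = as.character(utils::packageVersion("spliceflip")),
    outputs = sort(setdiff(list.files(out_dir, recursive = TRUE),
                           "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(state)
}
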
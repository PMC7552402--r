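# Synthetic-data generator: genotypes, covariates, abundances, reads,
# measurements.

test_that("genotype simulation is seed-deterministic and validates input", {
  b <- list(list(n_snps = 3, maf = 0.2, within_block_r2 = 0.9))
  g1 <- simulate_genotypes(50, b, n_independent = 2, seed = 7)
  g2 <- simulate_genotypes(50, b, n_independent = 2, seed = 7)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$snps, g2$snps)
  g3 <- simulate_genotypes(50, b, n_independent = 2, seed = 8)
  expect_false(identical(g1$dosages, g3$dosages))

  expect_error(simulate_genotypes(1, b, seed = 1), "n_samples")
  expect_error(simulate_genotypes(
    50, list(list(n_snps = 2, maf = 0.6, within_block_r2 = 1)), seed = 1),
    "maf")
  expect_error(simulate_genotypes(
    50, list(list(n_snps = 0, maf = 0.2, within_block_r2 = 1)), seed = 1),
    "n_snps")
  # positions strictly increasing, dosages in range
  expect_true(all(diff(g1$snps$position) > 0))
  expect_true(all(g1$dosages >= 0 & g1$dosages <= 2))
})

test_that("single-SNP genotype frequencies follow Hardy-Weinberg at maf 0.5", {
  g <- simulate_genotypes(10000, n_independent = 1, seed = 42,
                          independent_mafs = 0.5)
  d <- g$dosages[, 1]
  freq <- tabulate(d + 1, nbins = 3) / length(d)
  expected <- c(0.25, 0.5, 0.25)
  sds <- sqrt(expected * (1 - expected) / length(d))
  expect_true(all(abs(freq - expected) < 3 * sds))
})

test_that("a block with within_block_r2 = 1 duplicates haplotypes exactly", {
  g <- simulate_genotypes(
    400, list(list(n_snps = 5, maf = 0.3, within_block_r2 = 1.0)), seed = 3)
  r2 <- cor(g$dosages)^2
  expect_true(all(abs(r2 - 1) < 1e-12))
})

test_that("block copula hits the requested within-block r2", {
  g <- simulate_genotypes(
    4000, list(list(n_snps = 4, maf = 0.3, within_block_r2 = 0.8)), seed = 5)
  r2 <- cor(g$dosages)^2
  off <- r2[upper.tri(r2)]
  expect_true(all(abs(off - 0.8) < 0.08))
})

test_that("cohort simulation plants group sizes, GOLD stages and determinism", {
  cov <- simulate_cohort(100, n_copd = 40, seed = 9)
  expect_equal(sum(cov$fev1_fvc_ratio < 70), 40)
  expect_true(all(cov$gold_stage[cov$fev1_fvc_ratio >= 70] == "none"))
  expect_true(all(cov$gold_stage[cov$fev1_fvc_ratio < 70] != "none"))
  expect_identical(cov, simulate_cohort(100, n_copd = 40, seed = 9))
  expect_error(simulate_cohort(10, n_copd = 11, seed = 1), "n_copd")
  expect_true(all(cov$smoking %in% c("current", "ex")))
  expect_true(all(cov$pack_years >= 5))
})

test_that("abundance model reduces to baselines under the null", {
  w <- flip_world(n = 30, seed = 2)
  spec <- effect_spec(
    variants = list(V1 = list(baseline = 10), V2 = list(baseline = 30),
                    V3 = list(baseline = 20)),
    noise_sd = 0)
  ab <- simulate_variant_abundances(w$genotypes, w$covariates, w$gene, spec,
                                    seed = 1)
  expect_equal(unname(ab[, "V1"]), rep(10, 30))
  expect_equal(unname(ab[, "V2"]), rep(30, 30))
  expect_equal(unname(ab[, "V3"]), rep(20, 30))
})

test_that("log-linear means: coding rises while total falls for opposed betas", {
  # evaluate the stated generative means at dosage 0,1,2
  spec <- effect_spec(
    variants = list(
      V1 = list(baseline = 10, beta = c(s = +0.30)),
      V2 = list(baseline = 20, beta = c(s = -0.25)),
      V3 = list(baseline = 20, beta = c(s = -0.25))),
    noise_sd = 0)
  ex <- expected_abundances(spec, "s", 0:2)
  expect_equal(unname(ex[, "V1"]), 10 * exp(0.30 * (0:2)))
  total <- rowSums(ex)
  expect_true(all(diff(ex[, "V1"]) > 0))
  expect_true(all(diff(total) < 0))
})

test_that("default flip spec gives opposite analytic directions for probe vs total", {
  spec <- default_flip_spec("s")
  ex <- expected_abundances(spec, "s", 0:2)
  probe <- ex[, "V1"] + ex[, "V3"]   # probe junction spliced by V1 and V3
  total <- rowSums(ex)
  expect_true(all(diff(probe) > 0))
  expect_true(all(diff(total) < 0))
})

test_that("a COPD shift on the coding variant raises disease-group totals", {
  w <- flip_world(n = 200, seed = 4)
  spec <- effect_spec(
    variants = list(V1 = list(baseline = 10, disease_shift = 0.5),
                    V2 = list(baseline = 30), V3 = list(baseline = 20)),
    noise_sd = 0.05)
  ab <- simulate_variant_abundances(w$genotypes, w$covariates, w$gene, spec,
                                    seed = 5)
  copd <- w$covariates$fev1_fvc_ratio < 70
  expect_gt(mean(rowSums(ab[copd, ])), mean(rowSums(ab[!copd, ])))
})

test_that("abundance simulation rejects an incomplete effect spec", {
  w <- flip_world(n = 20, seed = 6)
  spec <- effect_spec(variants = list(V1 = list(baseline = 10)))
  expect_error(
    simulate_variant_abundances(w$genotypes, w$covariates, w$gene, spec),
    "missing entries")
})

test_that("coding-only reads carry exactly the annotated N spans", {
  gene <- tiny_gene()
  ab <- matrix(c(50, 0, 0), 1, 3, dimnames = list("S1", c("V1", "V2", "V3")))
  rs <- render_reads(ab, gene, read_length = 75, depth_factor = 100,
                     seed = 11)
  expect_gt(nrow(rs$reads), 0)
  jx <- extract_junctions(rs$reads$cigar, rs$reads$pos)
  ann <- gene$introns
  got <- unique(jx[, c("intron_start", "intron_end")])
  expect_setequal(paste(got$intron_start, got$intron_end),
                  paste(ann$start, ann$end))
  # every N span equals one annotated intron width
  expect_true(all(
    (jx$intron_end - jx$intron_start + 1) %in% (ann$end - ann$start + 1)))
})

test_that("zero abundance yields an empty read stream", {
  gene <- tiny_gene()
  ab <- matrix(0, 2, 3, dimnames = list(c("S1", "S2"), c("V1", "V2", "V3")))
  rs <- render_reads(ab, gene, seed = 1)
  expect_equal(nrow(rs$reads), 0)
  expect_error(render_reads(ab, gene, read_length = 0), "read_length")
})

test_that("split-read counts match the closed-form Poisson expectation", {
  gene <- tiny_gene()
  n <- 200
  set.seed(8)
  ab <- matrix(rep(c(10, 30, 20), each = n), n, 3,
               dimnames = list(sprintf("S%04d", 1:n), c("V1", "V2", "V3")))
  rl <- 75
  depth <- 100
  rs <- render_reads(ab, gene, read_length = rl, depth_factor = depth,
                     seed = 12)
  jc <- count_junctions(rs, gene)

  # closed form: E[count_J] = sum over variants splicing J of
  #   E[reads_v] * (#starts overlapping J) / (#starts total)
  expected_total <- function(intron_index) {
    tot <- 0
    for (v in names(gene$variants)) {
      if (!(intron_index %in% spliced_introns(gene, v))) next
      blocks <- spliceflip:::variant_blocks(gene, v)
      L <- sum(blocks$width)
      # transcript coordinate of the junction: cumulative width up to the
      # block preceding this gap
      gap_after_block <- which(
        blocks$end + 1 == gene$introns$start[intron_index])
      p <- cumsum(blocks$width)[gap_after_block]
      n_starts <- L - rl + 1
      overlap <- min(p, n_starts) - max(1, p - rl + 2) + 1
      tot <- tot + sum(ab[, v]) * depth * L / 1000 * overlap / n_starts
    }
    tot
  }
  for (ii in gene$introns$index) {
    key <- junction_key(gene$chrom, gene$introns$start[ii],
                        gene$introns$end[ii])
    obs <- sum(jc$counts[, key])
    exp_n <- expected_total(ii)
    expect_lt(abs(obs - exp_n), 3 * sqrt(exp_n))
  }
})

test_that("probe measurement equals log2 of detected abundance sum", {
  gene <- tiny_gene()
  ab <- matrix(c(10, 5, 3), 1, 3,
               dimnames = list("S1", c("V1", "V2", "V3")))
  # probe on the exon2-exon3 junction: detected variants V1 and V3
  ms <- render_measurements(ab, gene, probe_junction = 2,
                            noise_sd_probe = 0, seed = 1)
  expect_setequal(ms$detected_variants, c("V1", "V3"))
  expect_equal(unname(ms$probe_log2), log2(13), tolerance = 1e-12)
  expect_error(render_measurements(ab, gene, probe_junction = 9),
               "probe_junction")
})

test_that("probe signal is monotone in total when all variants share the junction", {
  # single-intron gene where both variants splice it
  gene <- gene_model("G2", "chr1", "+",
                     exons = data.frame(start = c(1, 501),
                                        end = c(300, 900)),
                     variants = list(splice_variant("A", coding = TRUE),
                                     splice_variant("B")))
  set.seed(2)
  ab <- matrix(runif(40, 1, 50), 20, 2,
               dimnames = list(sprintf("S%02d", 1:20), c("A", "B")))
  ms <- render_measurements(ab, gene, probe_junction = 1,
                            noise_sd_probe = 0, seed = 1)
  expect_equal(order(ms$probe_log2), order(ms$total_fpkm))
})

test_that("total FPKM is invariant to doubling abundance and library size", {
  gene <- tiny_gene()
  ab <- matrix(c(10, 5, 3, 2, 8, 4), 2, 3, byrow = TRUE,
               dimnames = list(c("S1", "S2"), c("V1", "V2", "V3")))
  m1 <- render_measurements(ab, gene, 2, noise_sd_probe = 0, seed = 1,
                            library_sizes = c(1e6, 2e6))
  m2 <- render_measurements(2 * ab, gene, 2, noise_sd_probe = 0, seed = 1,
                            library_sizes = 2 * c(1e6, 2e6))
  expect_equal(m1$total_fpkm, m2$total_fpkm, tolerance = 1e-12)
})

test_that("measurement and read rendering are seed-deterministic", {
  w <- flip_world(n = 25, seed = 3)
  ab <- simulate_variant_abundances(w$genotypes, w$covariates, w$gene,
                                    w$spec, seed = 21)
  r1 <- render_reads(ab, w$gene, depth_factor = 5, seed = 31)
  r2 <- render_reads(ab, w$gene, depth_factor = 5, seed = 31)
  expect_identical(r1$reads, r2$reads)
  m1 <- render_measurements(ab, w$gene, 2, seed = 41)
  m2 <- render_measurements(ab, w$gene, 2, seed = 41)
  expect_identical(m1$probe_log2, m2$probe_log2)
})
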
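# Junction extraction from CIGARs, counting, gene annotation, normalization.

test_that("worked junction coordinates from the reference walk", {
  j <- extract_junctions("50M200N50M", pos = 100)
  expect_equal(j$intron_start, 150)
  expect_equal(j$intron_end, 349)

  expect_equal(nrow(extract_junctions("100M", pos = 1)), 0)

  j2 <- extract_junctions("10M5I20M100N30M", pos = 1)
  expect_equal(j2$intron_start, 31)   # insertion consumes no reference
  expect_equal(j2$intron_end, 130)

  # soft/hard clips consume no reference either
  j3 <- extract_junctions("5S10M50N10M3H", pos = 100)
  expect_equal(j3$intron_start, 110)
  expect_equal(j3$intron_end, 159)
})

test_that("malformed CIGARs raise a parse error naming the token", {
  expect_error(extract_junctions("10M5B", 1), "5B")
  expect_error(extract_junctions("MM", 1), "malformed")
  expect_error(extract_junctions("10M-5N", 1), "malformed")
  expect_error(extract_junctions("10M", 0), "POS")
})

test_that("extract_junctions agrees with the per-base walk oracle", {
  set.seed(101)
  for (i in 1:100) {
    cg <- random_cigar()
    pos <- sample(1:5000, 1)
    got <- extract_junctions(cg, pos)
    want <- oracle_walk_junctions(cg, pos)
    expect_equal(nrow(got), nrow(want), info = cg)
    if (nrow(want)) {
      expect_equal(got$intron_start, want$intron_start, info = cg)
      expect_equal(got$intron_end, want$intron_end, info = cg)
    }
  }
})

make_reads <- function(sample_id, pos, cigar) {
  data.table::data.table(sample_id = sample_id, qname = seq_along(pos),
                         flag = 0L, rname = "chr22", pos = as.integer(pos),
                         mapq = 60L, cigar = cigar)
}

test_that("counting: identical split reads accumulate in one cell", {
  gene <- tiny_gene()
  i1 <- gene$introns
  cg <- sprintf("50M%dN50M", i1$end[1] - i1$start[1] + 1)
  reads <- make_reads("S1", rep(i1$start[1] - 50, 10), rep(cg, 10))
  jc <- count_junctions(reads, gene)
  expect_equal(nrow(jc$junctions), 1)
  expect_equal(unname(jc$counts["S1", 1]), 10)
  expect_equal(unname(jc$library_sizes["S1"]), 10)
})

test_that("a read with two N operations increments two junctions by one", {
  gene <- tiny_gene()
  it <- gene$introns
  w1 <- it$end[1] - it$start[1] + 1
  w2 <- it$end[2] - it$start[2] + 1
  gap_m <- it$start[2] - it$end[1] - 1   # exon 2 width
  cg <- sprintf("10M%dN%dM%dN10M", w1, gap_m, w2)
  reads <- make_reads("S1", it$start[1] - 10, cg)
  jc <- count_junctions(reads, gene)
  expect_equal(nrow(jc$junctions), 2)
  expect_equal(unname(jc$counts["S1", ]), c(1L, 1L))
  # conservation: total cells equal total N operations
  expect_equal(sum(jc$counts), 2)
})

test_that("junction counting conserves the number of N operations", {
  w <- flip_world(n = 10, seed = 5)
  ab <- simulate_variant_abundances(w$genotypes, w$covariates, w$gene,
                                    w$spec, seed = 6)
  rs <- render_reads(ab, w$gene, depth_factor = 5, seed = 7)
  jc <- count_junctions(rs, w$gene)
  n_ops_direct <- nrow(extract_junctions(rs$reads$cigar, rs$reads$pos))
  expect_equal(sum(jc$counts), n_ops_direct)
})

test_that("junctions inherit strand and gene from the containing gene model", {
  gene <- tiny_gene()
  it <- gene$introns
  cg <- sprintf("20M%dN20M", it$end[2] - it$start[2] + 1)
  inside <- make_reads("S1", it$start[2] - 20, cg)
  outside <- make_reads("S1", 1000, "30M500N30M")  # matches no gene
  jc <- count_junctions(rbind(inside, outside), gene)
  ann <- jc$junctions
  expect_equal(ann$strand[!is.na(ann$gene_id)], "+")
  expect_true(any(is.na(ann$gene_id)))
  expect_equal(ann$strand[is.na(ann$gene_id)], "unknown")
  expect_warning(normalize_junction_counts(jc), "without host gene")
})

test_that("multi-gene ambiguity resolves to the smallest containing span", {
  big <- gene_model("BIG", "chr22", "+",
                    exons = data.frame(start = c(23890000, 23900000),
                                       end = c(23894000, 23905000)),
                    variants = list(splice_variant("T1", coding = TRUE)))
  small <- tiny_gene()  # spans 23894000..23896999, inside BIG's span
  it <- small$introns
  cg <- sprintf("20M%dN20M", it$end[1] - it$start[1] + 1)
  reads <- make_reads("S1", it$start[1] - 20, cg)
  msgs <- capture_messages(jc <- count_junctions(reads, list(big, small)))
  expect_match(paste(msgs, collapse = " "), "smallest span")
  expect_equal(jc$junctions$gene_id, small$gene_id)
})

test_that("normalization is exactly invariant to a library-size factor", {
  gene <- tiny_gene()
  it <- gene$introns
  cg1 <- sprintf("20M%dN20M", it$end[1] - it$start[1] + 1)
  cg2 <- sprintf("20M%dN20M", it$end[2] - it$start[2] + 1)
  # three samples; sample C = sample A with every count doubled
  reads <- rbind(
    make_reads("A", rep(c(it$start[1] - 20, it$start[2] - 20), c(6, 4)),
               rep(c(cg1, cg2), c(6, 4))),
    make_reads("B", rep(c(it$start[1] - 20, it$start[2] - 20), c(5, 5)),
               rep(c(cg1, cg2), c(5, 5))),
    make_reads("C", rep(c(it$start[1] - 20, it$start[2] - 20), c(12, 8)),
               rep(c(cg1, cg2), c(12, 8)))
  )
  jn <- normalize_junction_counts(count_junctions(reads, gene))
  expect_equal(jn$values["A", ], jn$values["C", ], tolerance = 1e-12)
})

test_that("gene-wise correction removes a pure gene-expression factor", {
  gene <- tiny_gene()
  it <- gene$introns
  cg1 <- sprintf("20M%dN20M", it$end[1] - it$start[1] + 1)
  base <- function(s, mult = 1) {
    make_reads(s, rep(it$start[1] - 20, 4 * mult), rep(cg1, 4 * mult))
  }
  # sample C has the gene 3x higher overall with unchanged junction mix and
  # library size padded by reads from a second gene far away
  far <- gene_model("FAR", "chr22", "+",
                    exons = data.frame(start = c(23990000, 23991000),
                                       end = c(23990500, 23991500)),
                    variants = list(splice_variant("T", coding = TRUE)))
  pad <- function(s, n) make_reads(s, rep(23990100, n), rep("40M", n))
  reads <- rbind(base("A"), pad("A", 8),
                 base("B"), pad("B", 8),
                 base("C", mult = 3), pad("C", 0))
  jc <- count_junctions(reads, list(gene, far))
  jn <- normalize_junction_counts(jc)
  key <- jn$junctions$key[jn$junctions$gene_id == gene$gene_id]
  expect_equal(jn$values["A", key], jn$values["C", key], tolerance = 1e-12)
})

test_that("identical samples normalize to the library-scaled raw counts", {
  gene <- tiny_gene()
  it <- gene$introns
  cg1 <- sprintf("20M%dN20M", it$end[1] - it$start[1] + 1)
  reads <- rbind(make_reads("A", rep(it$start[1] - 20, 5), rep(cg1, 5)),
                 make_reads("B", rep(it$start[1] - 20, 5), rep(cg1, 5)),
                 make_reads("C", rep(it$start[1] - 20, 5), rep(cg1, 5)))
  jn <- normalize_junction_counts(count_junctions(reads, gene))
  expect_equal(unname(jn$values[, 1]), c(5, 5, 5))  # g_i = 1, lib factor 1
})

test_that("three-sample toy matrix matches the hand-evaluated formula", {
  # equal library sizes; single junction in its gene: normalized value
  # reduces to raw / gene-relative abundance. Gene totals differ only
  # through a second, junction-free gene region is absent, so the gene
  # factor is count/median(count).
  gene <- tiny_gene()
  it <- gene$introns
  cg1 <- sprintf("20M%dN20M", it$end[1] - it$start[1] + 1)
  pad_pos <- gene$exons$start[1]   # plain exonic reads, same gene
  reads <- rbind(
    make_reads("A", c(rep(it$start[1] - 20, 1), rep(pad_pos, 9)),
               c(rep(cg1, 1), rep("30M", 9))),
    make_reads("B", c(rep(it$start[1] - 20, 2), rep(pad_pos, 8)),
               c(rep(cg1, 2), rep("30M", 8))),
    make_reads("C", c(rep(it$start[1] - 20, 4), rep(pad_pos, 6)),
               c(rep(cg1, 4), rep("30M", 6)))
  )
  jn <- normalize_junction_counts(count_junctions(reads, gene))
  # library sizes all 10 -> lib factor 1; gene totals all 10 -> g_i = 1;
  # normalized = raw
  expect_equal(unname(jn$values[, 1]), c(1, 2, 4))
})

test_that("junction TSV writer round-trips the count matrix", {
  w <- flip_world(n = 6, seed = 9)
  ab <- simulate_variant_abundances(w$genotypes, w$covariates, w$gene,
                                    w$spec, seed = 2)
  jc <- count_junctions(render_reads(ab, w$gene, depth_factor = 5, seed = 3),
                        w$gene)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_junction_tsv(jc, path)
  d <- as.data.frame(data.table::fread(path))
  expect_equal(nrow(d), nrow(jc$junctions))
  sample_cols <- setdiff(names(d), c("chrom", "strand", "intron_start",
                                     "intron_end", "gene_id"))
  expect_equal(as.matrix(t(d[, sample_cols])), jc$counts,
               ignore_attr = TRUE)
})
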
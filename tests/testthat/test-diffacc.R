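peak_gr <- function(start0, end0, id = sprintf("p%d", seq_along(start0))) {
  GenomicRanges::GRanges("chr1", IRanges::IRanges(start0 + 1L, end0), name = id)
}

frag_dt <- function(start0, end0, sample = "s1") {
  data.table::data.table(chrom = "chr1", start = start0, end = end0,
                         sample = sample)
}

test_that("fragment counting follows the >= 1 bp half-open overlap rule", {
  peaks <- peak_gr(140, 200)
  expect_equal(as.integer(count_fragments(frag_dt(100, 150), peaks)), 1L)
  # fragment abutting the peak start (end == start) does not overlap
  expect_equal(as.integer(count_fragments(frag_dt(100, 140), peaks)), 0L)
  cts <- count_fragments(frag_dt(c(150, 160, 170, 500),
                                 c(190, 199, 195, 560)), peaks)
  expect_equal(as.integer(cts), 3L)
})

test_that("counting conserves fragments over disjoint peaks", {
  pl <- count_pipeline()
  fgr <- GenomicRanges::GRanges(pl$fragments$fragments$chrom,
    IRanges::IRanges(pl$fragments$fragments$start + 1L, pl$fragments$fragments$end))
  # union counting: one increment per (fragment, peak) overlap pair
  direct <- length(GenomicRanges::findOverlaps(fgr, pl$sim$peaks,
                                               ignore.strand = TRUE))
  expect_equal(sum(pl$counts), direct)
  # and never fewer than the number of fragments touching any peak
  expect_gte(sum(pl$counts), sum(IRanges::overlapsAny(fgr, pl$sim$peaks)))
})

test_that("a sample with zero fragments is an error", {
  expect_error(count_fragments(frag_dt(100, 150), peak_gr(0, 1000),
                               samples = c("s1", "s2")), "s2")
})

test_that("degenerate count matrices give null statistics", {
  counts <- matrix(rep(c(5L, 9L, 13L), each = 4), nrow = 3, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), NULL))
  res <- nb_differential(counts, c("x", "x", "y", "y"))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3))
  # all-zero peak convention
  counts0 <- rbind(counts, z = 0L)
  res0 <- nb_differential(counts0, c("x", "x", "y", "y"))
  expect_equal(res0$pvalue[4], 1)
  expect_equal(res0$log2fc[4], 0)
})

test_that("doubling one sample doubles its size factor", {
  set.seed(2)
  counts <- matrix(rnbinom(400, mu = 80, size = 10), ncol = 4)
  counts <- cbind(counts, 2L * counts[, 4])
  sf <- size_factors(counts)
  expect_equal(sf[5] / sf[4], 2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("nb_differential validates its design", {
  counts <- matrix(1L, 4, 3)
  expect_error(nb_differential(counts, c("x", "x", "y")), ">= 2 samples")
  expect_error(nb_differential(matrix(-1L, 2, 4), c("x", "x", "y", "y")),
               "non-negative")
})

test_that("signed ranking follows the direction-aware p-value rule", {
  st <- data.frame(id = c("A", "B", "C"), pvalue = c(0.01, 0.5, 0.01),
                   log2fc = c(1, 1, -1))
  expect_equal(rank_peaks(st)$rank, c(1L, 2L, 3L))
  # all same sign, equal p: stable input order
  st2 <- data.frame(id = letters[1:4], pvalue = 0.2, log2fc = 1)
  expect_equal(rank_peaks(st2)$rank, 1:4)
  # zero fold changes sit between, by descending p
  st3 <- data.frame(id = c("open", "z1", "z2", "close"),
                    pvalue = c(0.01, 0.2, 0.9, 0.05),
                    log2fc = c(2, 0, 0, -2))
  expect_equal(rank_peaks(st3)$rank, c(1L, 3L, 2L, 4L))
  expect_error(rank_peaks(data.frame(pvalue = c(0.1, NA), log2fc = 1)),
               "missing")
})

test_that("ranks are always a permutation and states split the ranking", {
  pl <- count_pipeline()
  r <- pl$ranked
  expect_setequal(r$rank, seq_len(nrow(r)))
  expect_true(max(r$rank[r$state == "opening"]) <
              min(r$rank[r$state == "closing"]))
})

test_that("dynamic classification applies the Bonferroni rule", {
  st <- data.frame(id = c("a", "b"), pvalue = c(0.001, 0.2),
                   log2fc = c(1, -1), padj = pmin(1, c(0.001, 0.2) * 4))
  cl <- classify_dynamic(st, 0.05)
  expect_equal(cl$state, c("opening", "unchanged"))
  expect_error(classify_dynamic(st, 1.5), "alpha")
})

test_that("annotation precedence is upstream > exon > intron > intergenic", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, width = 1),
                                  strand = "+", gene_id = "g1")
  exons <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(50001, 70001), width = 200), strand = "+",
    gene_id = c("g1", "g1"))
  peaks <- peak_gr(c(44999, 60000, 69950, 200000),
                   c(45300, 60400, 70300, 200400))
  cat <- annotate_peaks(peaks, genes, exons)
  expect_equal(cat, c("upstream_10kb", "intron", "exon", "intergenic"))
  # a peak overlapping both an exon and an upstream window is upstream
  genes2 <- c(genes, GenomicRanges::GRanges("chr1",
    IRanges::IRanges(70500, width = 1), strand = "+", gene_id = "g2"))
  expect_equal(annotate_peaks(peaks, genes2, exons)[3], "upstream_10kb")
  expect_error(annotate_peaks(peaks, GenomicRanges::GRanges(), exons), "genes")
})

test_that("peak overlap fraction handles identity, disjoint and partial sets", {
  a <- peak_gr(c(0, 100, 200), c(50, 150, 250))
  expect_equal(peak_overlap_fraction(a, a)$fraction, 1)
  b <- peak_gr(c(1000, 2000), c(1100, 2100))
  expect_equal(peak_overlap_fraction(a, b)$fraction, 0)
  c_ <- peak_gr(c(40, 140), c(60, 160))
  expect_equal(peak_overlap_fraction(a, c_)$fraction, 2 / 3, tolerance = 1e-9)
  expect_error(peak_overlap_fraction(GenomicRanges::GRanges(), a), "empty")
})

test_that("rank-bin frequencies partition the ranking", {
  ranked <- data.frame(id = sprintf("p%02d", 1:20), rank = 1:20)
  rb <- rank_bin_frequency(ranked, hits = sprintf("p%02d", 1:10), bin_size = 10)
  expect_equal(rb$fraction, c(1, 0))
  expect_equal(sum(rb$n), 20L)
  expect_error(rank_bin_frequency(ranked, "p01", bin_size = 0), "bin_size")
  # uniformly random hits stay flat within binomial noise
  set.seed(4)
  ranked2 <- data.frame(id = sprintf("q%04d", 1:2000), rank = 1:2000)
  hits <- sample(ranked2$id, 400)
  rb2 <- rank_bin_frequency(ranked2, hits, bin_size = 500)
  expect_true(all(abs(rb2$fraction - 0.2) < 3 * sqrt(0.2 * 0.8 / 500)))
})

test_that("fold changes and calls agree with DESeq2 as an independent check", {
  set.seed(91)
  m <- 300
  mu <- rlnorm(m, log(100), 0.5)
  fc <- rep(1, m)
  fc[1:30] <- 4                          # planted opening
  fc[31:45] <- 0.25                      # planted closing
  cts <- cbind(
    matrix(rnbinom(m * 3, mu = mu, size = 20), m),
    matrix(rnbinom(m * 3, mu = mu * fc, size = 20), m))
  rownames(cts) <- sprintf("p%03d", seq_len(m))
  cond <- rep(c("ctrl", "dec"), each = 3)
  mine <- nb_differential(cts, cond)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cts, S4Vectors::DataFrame(condition = factor(cond)), ~condition)
  dres <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  expect_gt(cor(mine$log2fc, dres$log2FoldChange), 0.98)
  top_mine <- rownames(cts)[order(mine$pvalue)[1:45]]
  top_deseq <- rownames(cts)[order(dres$pvalue)[1:45]]
  expect_gte(length(intersect(top_mine, top_deseq)), 40)
})

test_that("label permutations of null simulations give uniform p-values", {
  # one random balanced relabeling per independent null dataset: repeated
  # permutations of one dataset are mutually dependent and would invalidate
  # the KS test
  set.seed(6)
  ps <- c()
  for (i in 1:5) {
    cfg <- sim_config(seed = 170 + i, genome_length = 1e6, n_peaks = 250,
                      n_opening = 0, n_closing = 0, effect_log2fc = 0,
                      n_genes = 40)
    sim <- simulate_genome(cfg, sequence = FALSE)
    fr <- simulate_fragments(sim)
    cts <- count_fragments(fr$fragments, sim$peaks, samples = fr$samples$sample)
    ps <- c(ps, nb_differential(cts, sample(fr$samples$condition))$pvalue)
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("planted dynamic peaks are recovered with high precision and recall", {
  pl <- count_pipeline()
  truth <- pl$truth
  called <- pl$ranked$state != "unchanged"
  correct <- called & truth == pl$ranked$state
  expect_gte(sum(correct) / sum(called), 0.95)
  expect_gte(sum(correct) / sum(truth != "unchanged"), 0.9)
})
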
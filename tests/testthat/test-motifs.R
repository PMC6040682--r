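test_that("matched background intervals respect width, location and GC bins", {
  sim <- small_sim()
  peaks <- sim$peaks[1:30]
  bg <- suppressWarnings(sample_matched_background(peaks, sim$genome, sim$genes,
                                                   n_per_input = 2L, seed = 5))
  expect_length(bg, 60)
  expect_equal(unique(GenomicRanges::width(bg)),
               unique(GenomicRanges::width(peaks)))
  # every background interval within 50 kb of some TSS
  near <- GenomicRanges::resize(sim$genes, width = 100001L, fix = "center")
  expect_true(all(IRanges::overlapsAny(bg, near)))
  # GC bins match their input peak except recorded fallbacks
  gc_in <- gc_content(extract_interval_seqs(sim$genome, peaks))
  same_bin <- floor(S4Vectors::mcols(bg)$gc / 0.05) ==
    floor(gc_in[S4Vectors::mcols(bg)$matched_peak] / 0.05)
  expect_gte(sum(same_bin), length(bg) - S4Vectors::mcols(bg)$fallback_count[1])
  # determinism
  bg2 <- suppressWarnings(sample_matched_background(peaks, sim$genome, sim$genes,
                                                    n_per_input = 2L, seed = 5))
  expect_identical(GenomicRanges::start(bg), GenomicRanges::start(bg2))
})

test_that("background GC distribution matches the input peaks", {
  sim <- small_sim()
  peaks <- sim$peaks
  bg <- suppressWarnings(sample_matched_background(peaks, sim$genome, sim$genes,
                                                   seed = 2))
  gc_in <- gc_content(extract_interval_seqs(sim$genome, peaks))
  gc_bg <- S4Vectors::mcols(bg)$gc
  bins <- seq(0, 1, 0.05)
  tab <- rbind(table(cut(gc_in, bins)), table(cut(gc_bg, bins)))
  keep <- colSums(tab) > 0
  expect_gt(suppressWarnings(stats::chisq.test(tab[, keep]))$p.value, 0.01)
})

test_that("motif enrichment reports exact-test odds ratios", {
  # construction: 30/100 targets vs 10/100 backgrounds carry the motif
  site <- "TGACTCA"
  set.seed(31)
  # G-free backbone: the site (and its reverse complement) cannot occur by
  # chance, so motif counts are exactly the planted ones
  mk <- function(n, n_with) {
    Biostrings::DNAStringSet(vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "T"), 120, replace = TRUE), collapse = "")
      if (i <= n_with) substr(s, 50, 56) <- site
      s
    }, character(1)))
  }
  cal <- pwm_score_threshold(pwm_from_consensus("bzip_like", site), 1e-4)
  en <- motif_enrichment(mk(100, 30), mk(100, 10), cal)
  expect_equal(en$target_pct, 30)
  expect_equal(en$background_pct, 10)
  expect_equal(en$odds_ratio, (30 * 90) / (70 * 10), tolerance = 1e-9)
  expect_equal(en$p, fisher.test(matrix(c(30, 70, 10, 90), 2, byrow = TRUE))$p.value)
  # identity: identical sets give OR 1, p 1
  tg <- mk(50, 20)
  en2 <- motif_enrichment(tg, tg, cal)
  expect_equal(en2$odds_ratio, 1)
  expect_equal(en2$p, 1)
  # swapping target and background inverts the odds ratio
  en3 <- motif_enrichment(mk(100, 10), mk(100, 30), cal)
  expect_equal(en3$odds_ratio, 1 / en$odds_ratio, tolerance = 1e-9)
  expect_error(motif_enrichment(Biostrings::DNAStringSet(), tg, cal), "empty")
})

test_that("triple-motif scan enforces order, gaps, span and strand", {
  pw <- synthetic_pwms()
  cals <- lapply(pw, pwm_score_threshold, alpha = 1e-4)
  set.seed(41)
  gap <- "CTCTA"
  good <- paste0(random_dna(60), "GGTCACAGTGACC", gap, "TGACTCA", gap,
                 "GTCACGCTTGA", random_dna(60))
  wrong_order <- paste0(random_dna(60), "GTCACGCTTGA", gap, "TGACTCA", gap,
                        "GGTCACAGTGACC", random_dna(60))
  wide <- paste0(random_dna(60), "GGTCACAGTGACC", strsplit(random_dna(30), "")[[1]] |>
                   paste(collapse = ""), "TGACTCA", gap, "GTCACGCTTGA",
                 random_dna(60))
  seqs <- Biostrings::DNAStringSet(c(good = good, wrong = wrong_order, wide = wide))
  hits <- find_triple_motif(seqs, cals$esr, cals$bzip, cals$pax)
  expect_equal(as.character(GenomicRanges::seqnames(hits)), "good")
  expect_equal(GenomicRanges::start(hits), 61)
  expect_equal(as.character(GenomicRanges::strand(hits)), "+")
  # reverse-complemented arrangement is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(good)))
  hits_rc <- find_triple_motif(Biostrings::DNAStringSet(c(m = rc)),
                               cals$esr, cals$bzip, cals$pax)
  expect_equal(as.character(GenomicRanges::strand(hits_rc)), "-")
  expect_error(find_triple_motif(seqs, cals$esr, cals$bzip, cals$pax,
                                 max_span = 20), "max_span")
})

test_that("triple-motif scan equals the brute-force join on random genomes", {
  pw <- synthetic_pwms(p_consensus = 0.75)   # softer PWMs give chance hits
  cals <- lapply(pw, pwm_score_threshold, alpha = 3e-3)
  set.seed(51)
  for (trial in 1:4) {
    s <- random_dna(30000)
    seqs <- Biostrings::DNAStringSet(setNames(s, sprintf("g%d", trial)))
    e <- scan_pwm(seqs, cals$esr)
    b <- scan_pwm(seqs, cals$bzip)
    p <- scan_pwm(seqs, cals$pax)
    got <- triple_key(combine_hits(e, b, p, max_span = 60L, gap_range = c(0L, 25L)))
    want <- brute_force_triples(e, b, p, max_span = 60L, gap_range = c(0L, 25L))
    expect_identical(got, want)
  }
})

test_that("every planted Alu copy yields exactly one triple hit, in its 3' half", {
  sim <- small_sim()
  pw <- synthetic_pwms()
  cals <- lapply(pw, pwm_score_threshold, alpha = 1e-4)
  hits <- find_triple_motif(sim$genome, cals$esr, cals$bzip, cals$pax)
  n_cores <- sum(!is.na(S4Vectors::mcols(sim$repeats)$triple_gstart))
  expect_equal(length(hits), n_cores)
  ov <- triple_motif_repeat_overlap(hits, sim$repeats)
  expect_equal(ov$alu_three_prime_fraction, 1)
  expect_equal(unname(ov$family_counts["Alu"]), length(hits), ignore_attr = TRUE)
})

test_that("motif frequency decreases along the accessibility ranking", {
  sim <- small_sim()
  fr <- small_fragments()
  cts <- count_fragments(fr$fragments, sim$peaks, samples = fr$samples$sample)
  ranked <- rank_peaks(nb_differential(cts, fr$samples$condition))
  cal <- pwm_score_threshold(synthetic_pwms()$bzip, 1e-4)
  hits <- scan_pwm(extract_interval_seqs(sim$genome, sim$peaks), cal)
  bearing <- unique(as.character(GenomicRanges::seqnames(hits)))
  rb <- rank_bin_frequency(ranked, bearing, bin_size = 25L)
  # motif-driven opening concentrates motif-bearing peaks in the first bin
  expect_gt(rb$fraction[1], max(rb$fraction[-1]))
  expect_gt(rb$fraction[1], rb$fraction[nrow(rb)])
})

test_that("repeat assignment is strand-aware about the 3' half", {
  reps <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1001, 5001), width = 300),
                                 strand = c("+", "-"),
                                 family = c("Alu", "Alu"))
  hits <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1260, 5020, 9000), width = 30),
                                 strand = "+",
                                 esr_start = 1L, esr_end = 2L, bzip_start = 1L,
                                 bzip_end = 2L, pax_start = 1L, pax_end = 2L)
  ov <- triple_motif_repeat_overlap(hits, reps)
  expect_equal(ov$per_hit$family, c("Alu", "Alu", "none"))
  # + strand: genomic right half is 3'; - strand: genomic left half is 3'
  expect_true(ov$per_hit$three_prime[1])
  expect_true(ov$per_hit$three_prime[2])
})
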
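#!/usr/bin/env Rscript
# Motif enrichment of dynamic peaks against GC/CpG-matched backgrounds,
# motif frequency across the accessibility ranking, and strand-specific
# Tn5 footprint profiles around planted bZIP sites.

source("analysis/00_config.R")

sim <- simulate_genome(sequence_config())
fr <- simulate_fragments(sim)
cts <- count_fragments(fr$fragments, sim$peaks, samples = fr$samples$sample)
ranked <- classify_dynamic(rank_peaks(nb_differential(cts, fr$samples$condition)))

pw <- read_pwm(system.file("extdata", "motifs_synthetic.meme",
                           package = "stromatac"))
cals <- lapply(pw, pwm_score_threshold, alpha = 1e-4)

## enrichment of each motif in opening peaks vs matched background
opening <- sim$peaks[ranked$state == "opening"]
bg <- suppressWarnings(sample_matched_background(
  opening, sim$genome, sim$genes, n_per_input = 3L, seed = SEED))
enr <- lapply(names(cals), function(m) {
  e <- motif_enrichment(opening, bg, cals[[m]], sim$genome)
  data.frame(motif = m, target_pct = e$target_pct,
             background_pct = e$background_pct, odds_ratio = e$odds_ratio,
             p = e$p)
})
enr <- do.call(rbind, enr)
write_table(enr, "motif_enrichment.tsv")
message(sprintf("bZIP motif: %.0f%% of opening peaks vs %.0f%% of matched background (p = %.2g)",
                enr$target_pct[enr$motif == "bzip_like"],
                enr$background_pct[enr$motif == "bzip_like"],
                enr$p[enr$motif == "bzip_like"]))

## motif frequency across the full ranking, in rank bins
peak_seqs <- extract_interval_seqs(sim$genome, sim$peaks)
hits_bzip <- scan_pwm(peak_seqs, cals$bzip_like)
bearing <- unique(as.character(GenomicRanges::seqnames(hits_bzip)))
bg_seqs <- extract_interval_seqs(sim$genome, bg)
bg_hits <- scan_pwm(bg_seqs, cals$bzip_like)
expected_frac <- length(unique(as.character(GenomicRanges::seqnames(bg_hits)))) /
  length(bg_seqs)
rb <- rank_bin_frequency(ranked, bearing, bin_size = 25L,
                         expected = expected_frac)
write_table(rb[, c("bin", "rank_lo", "rank_hi", "n", "n_hits", "fraction")],
            "bzip_rank_bins.tsv")
message(sprintf("bZIP frequency, first vs last rank bin: %.2f vs %.2f",
                rb$fraction[1], rb$fraction[nrow(rb)]))

## aggregate footprint profile over occupied sites
cuts <- suppressWarnings(fragments_to_cuts(fr$fragments))
occ <- sim$motif_sites[S4Vectors::mcols(sim$motif_sites)$occupied]
uno <- sim$motif_sites[!S4Vectors::mcols(sim$motif_sites)$occupied]
prof <- aggregate_profile(cuts, occ)
write_table(data.frame(offset = prof$offset, plus_mean = prof$plus,
                       minus_mean = prof$minus), "footprint_profile.tsv")
fd <- footprint_depth(prof)
auc <- roc_auc(footprint_depth_per_site(cuts, occ),
               footprint_depth_per_site(cuts, uno))
message(sprintf("occupied sites: depth %.2f, asymmetry %+.2f; occupied-vs-unoccupied AUC %.3f",
                fd$depth, fd$asymmetry, auc))
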
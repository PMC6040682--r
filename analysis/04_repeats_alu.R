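#!/usr/bin/env Rscript
# Transposable elements and the triple motif: genome-wide triple-motif scan
# and its overlap with Alu 3' halves, TE-family overlap enrichment,
# per-consensus-position overlap/entropy/cut profiles, and the 5'-vs-3'
# end asymmetry test.

source("analysis/00_config.R")

sim <- simulate_genome(sequence_config())
fr <- simulate_fragments(sim)
cuts <- suppressWarnings(fragments_to_cuts(fr$fragments))

pw <- read_pwm(system.file("extdata", "motifs_synthetic.meme",
                           package = "stromatac"))
cals <- lapply(pw, pwm_score_threshold, alpha = 1e-4)

## triple motif: genome-wide scan and repeat assignment
trip <- find_triple_motif(sim$genome, cals$esr_like, cals$bzip_like,
                          cals$pax_like)
ovl <- triple_motif_repeat_overlap(trip, sim$repeats)
write_table(data.frame(family = names(ovl$family_counts),
                       n_hits = as.integer(ovl$family_counts)),
            "triple_motif_families.tsv")
message(sprintf("%d triple motifs found; fraction in Alu 3' halves: %.2f",
                length(trip), ovl$alu_three_prime_fraction))

## TE family overlap enrichment (Fisher, bp resolution)
fam <- family_overlap_enrichment(sim$peaks, sim$repeats,
                                 sim$config$genome_length)
write_table(fam[, c("family", "family_bp", "overlap_bp", "expected_bp",
                    "odds_ratio", "p", "direction")],
            "te_family_enrichment.tsv")
message("TE families over-represented in peaks: ",
        paste(fam$family[fam$direction == "over" & fam$p < 0.01], collapse = ", "))

## Alu consensus-coordinate profiles
alu <- sim$repeats[S4Vectors::mcols(sim$repeats)$family == "Alu"]
pof <- position_overlap_frequency(alu, sim$peaks)
write_table(pof, "alu_position_overlap.tsv")
ep <- entropy_profile(consensus_base_matrix(alu, sim$genome))
write_table(ep, "alu_entropy_profile.tsv")
cp <- aggregate_cut_profile_over_elements(cuts, alu)
write_table(data.frame(position = cp$offset, plus_mean = cp$plus,
                       minus_mean = cp$minus), "alu_cut_profile.tsv")

ea <- end_asymmetry_test(alu, sim$peaks)
write_table(data.frame(n_3prime_only = ea$n_3prime_only,
                       n_5prime_only = ea$n_5prime_only, p = ea$p,
                       direction = ea$direction), "alu_end_asymmetry.tsv")
message(sprintf("end asymmetry: %d 3'-only vs %d 5'-only instances (binomial p = %.2g, %s)",
                ea$n_3prime_only, ea$n_5prime_only, ea$p, ea$direction))
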
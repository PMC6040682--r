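#!/usr/bin/env Rscript
# Differential chromatin accessibility at the full study design: fragment
# counting in peaks, the NB Wald test, signed ranking, Bonferroni dynamic
# classification, genomic annotation, and recovery scoring against the
# planted truth.

source("analysis/00_config.R")

sim <- simulate_genome(counts_config(), sequence = FALSE)
fr <- simulate_fragments(sim)
cts <- count_fragments(fr$fragments, sim$peaks, samples = fr$samples$sample)
res <- classify_dynamic(rank_peaks(nb_differential(cts, fr$samples$condition)))
res$category <- annotate_peaks(sim$peaks, sim$genes, sim$exons)

tbl <- cbind(
  data.frame(chrom = as.character(GenomicRanges::seqnames(sim$peaks)),
             start = GenomicRanges::start(sim$peaks) - 1L,
             end = GenomicRanges::end(sim$peaks)),
  res)
write_table(tbl, "differential_accessibility.tsv")

truth <- S4Vectors::mcols(sim$peaks)$state
called <- res$state != "unchanged"
correct <- called & truth == res$state
message(sprintf("opening called: %d / %d planted; closing: %d / %d planted",
                sum(res$state == "opening"), sum(truth == "opening"),
                sum(res$state == "closing"), sum(truth == "closing")))
message(sprintf("precision %.3f, recall %.3f (Bonferroni 0.05)",
                sum(correct) / sum(called), sum(correct) / sum(truth != "unchanged")))

cat_frac <- prop.table(table(res$category[called]))
write_table(data.frame(category = names(cat_frac),
                       fraction_of_dynamic_peaks = as.numeric(cat_frac)),
            "dynamic_peak_categories.tsv")
message("dynamic peak genomic categories: ",
        paste(sprintf("%s %.0f%%", names(cat_frac), 100 * cat_frac), collapse = ", "))
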
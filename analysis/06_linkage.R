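#!/usr/bin/env Rscript
# Peak-to-gene linkage and expression association: do genes near the most
# opening / most closing peaks move in the matching direction?

source("analysis/00_config.R")

sim <- simulate_genome(counts_config(), sequence = FALSE)
fr <- simulate_fragments(sim)
cts <- count_fragments(fr$fragments, sim$peaks, samples = fr$samples$sample)
ranked <- classify_dynamic(rank_peaks(nb_differential(cts, fr$samples$condition)))
expr <- simulate_expression(sim)
links <- link_peaks_to_genes(sim$peaks, sim$genes)
write_table(links, "peak_gene_links.tsv")

g <- group_expression_change(ranked, links, expr)
write_table(g$values, "expression_groups.tsv")
write_table(data.frame(mean_opening = g$mean_opening,
                       mean_closing = g$mean_closing,
                       t = g$t, p = g$p,
                       n_opening = g$n_opening, n_closing = g$n_closing),
            "expression_association.tsv")
message(sprintf(
  "genes near top-100 opening peaks: mean log2fc %+.2f (n=%d); closing: %+.2f (n=%d); Welch t = %.1f, p = %.2g",
  g$mean_opening, g$n_opening, g$mean_closing, g$n_closing, g$t, g$p))
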
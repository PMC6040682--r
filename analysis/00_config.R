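# Shared settings for the analysis drivers. Two simulated studies are used:
# a counts-scale study at the full design (5000 peaks, 200/50 dynamic) for
# the differential-accessibility and linkage analyses, and a sequence-scale
# study (400 kb with genome sequence) for the motif, footprint, repeat and
# conservation analyses.

library(stromatac)

SEED <- 1L
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

counts_config <- function() sim_config(seed = SEED)

sequence_config <- function() sim_config(
  seed = SEED + 1L, genome_length = 4e5, n_peaks = 200, n_opening = 25,
  n_closing = 8, n_genes = 60, peak_width = 300)

write_table <- function(x, name) {
  path <- file.path(RESULTS, name)
  data.table::fwrite(as.data.frame(x), path, sep = "\t")
  message("wrote ", path)
  path
}
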
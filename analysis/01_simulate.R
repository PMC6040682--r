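#!/usr/bin/env Rscript
# Generate the simulated study inputs and write them in their on-disk
# formats (FASTA, narrowPeak, BED, RepeatMasker .out, fragment TSVs), so the
# downstream drivers can be pointed at files exactly as a real study would.

source("analysis/00_config.R")

sim <- simulate_genome(sequence_config())
fr <- simulate_fragments(sim)
expr <- simulate_expression(sim)
write_sim(sim, file.path(RESULTS, "sim_data"), fragments = fr, expression = expr)

n_alu <- sum(S4Vectors::mcols(sim$repeats)$family == "Alu")
message(sprintf(
  "simulated %s bp genome: %d peaks (%d opening, %d closing), %d genes, %d repeats (%d Alu), %s fragments",
  format(sim$config$genome_length, big.mark = ",", scientific = FALSE), length(sim$peaks),
  sum(S4Vectors::mcols(sim$peaks)$state == "opening"),
  sum(S4Vectors::mcols(sim$peaks)$state == "closing"),
  length(sim$genes), length(sim$repeats), n_alu,
  format(nrow(fr$fragments), big.mark = ",")))
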
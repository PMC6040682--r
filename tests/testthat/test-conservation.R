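mk_genome <- function(s, name = "ref") {
  g <- Biostrings::DNAStringSet(s)
  names(g) <- name
  g
}

test_that("flank queries span the element junctions, strand-aware", {
  set.seed(61)
  g <- mk_genome(random_dna(3000))
  inst <- GenomicRanges::GRanges("ref", IRanges::IRanges(1001, 1300),
                                 strand = "+", name = "L1")
  fq <- extract_flank_queries(inst, g)
  expect_equal(names(fq$queries), c("L1|q5", "L1|q3"))
  gs <- as.character(g[[1]])
  expect_equal(as.character(fq$queries[["L1|q5"]]), substr(gs, 951, 1050))
  expect_equal(as.character(fq$queries[["L1|q3"]]), substr(gs, 1251, 1350))
  # minus strand: q5/q3 swap and reverse-complement
  minus <- inst
  GenomicRanges::strand(minus) <- "-"
  fqm <- extract_flank_queries(minus, g)
  expect_equal(as.character(fqm$queries[["L1|q5"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(substr(gs, 1251, 1350)))))
  # an instance too close to the contig edge is excluded with a reason
  edge <- GenomicRanges::GRanges("ref", IRanges::IRanges(21, 320),
                                 strand = "+", name = "E1")
  fqe <- extract_flank_queries(edge, g)
  expect_equal(nrow(fqe$info), 0L)
  expect_equal(fqe$excluded$locus_id, "E1")
})

test_that("query mapping finds unique verbatim hits and rejects ambiguity", {
  set.seed(62)
  uniq <- random_dna(100)
  dup <- random_dna(100)
  target <- mk_genome(paste0(random_dna(500), uniq, random_dna(400), dup,
                             random_dna(300), dup, random_dna(200)), "t")
  q <- Biostrings::DNAStringSet(c(u = uniq, d = dup))
  mq <- map_queries(q, target)
  expect_true(mq$mapped[mq$query_id == "u"])
  expect_equal(mq$boundary_tpos0[mq$query_id == "u"], 500L + 50L)
  expect_equal(mq$id_first50[mq$query_id == "u"], 1)
  # duplicated target site: ambiguous, unmapped
  expect_false(mq$mapped[mq$query_id == "d"])
  # ~10% substitutions still map above the 80% identity floor
  mut <- strsplit(uniq, "")[[1]]
  idx <- sample(100, 10)
  mut[idx] <- vapply(mut[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  mq2 <- map_queries(Biostrings::DNAStringSet(c(m = paste(mut, collapse = ""))), target)
  expect_true(mq2$mapped[1])
  expect_error(map_queries(q), "target genome or")
})

test_that("reverse-complemented queries map with minus orientation", {
  set.seed(63)
  uniq <- random_dna(100)
  target <- mk_genome(paste0(random_dna(400), uniq, random_dna(400)), "t")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(uniq)))
  mq <- map_queries(Biostrings::DNAStringSet(c(r = rc)), target)
  expect_true(mq$mapped[1])
  expect_equal(mq$orientation[1], "-")
})

test_that("presence calls follow the span and junction rules", {
  hit <- function(mapped = TRUE, b = 0L, ori = "+", id_in = 1, id_out = 1,
                  subject = "t") {
    data.table::data.table(mapped = mapped, subject = subject,
                           orientation = ori, boundary_tpos0 = b,
                           id_first50 = id_out, id_last50 = id_in)
  }
  # D = element length, junctions intact -> present
  q5 <- hit(b = 1000L)                      # q5: first50 outer, last50 inner
  q3 <- hit(b = 1300L, id_in = 1, id_out = 1)
  q3$id_first50 <- 1                        # q3 inner half
  expect_equal(call_presence(q5, q3, 300)$state, "present")
  # flanks nearly adjacent -> absent
  expect_equal(call_presence(hit(b = 1000L), hit(b = 1010L), 300)$state, "absent")
  # unmapped q3 -> inconclusive
  expect_equal(call_presence(hit(b = 1000L), hit(mapped = FALSE), 300)$state,
               "inconclusive")
  # different orientation -> inconclusive
  expect_equal(call_presence(hit(b = 1000L), hit(b = 1300L, ori = "-"), 300)$state,
               "inconclusive")
  # span right but junction broken -> not present
  broken <- hit(b = 1300L)
  broken$id_first50 <- 0.3
  expect_equal(call_presence(q5, broken, 300)$state, "inconclusive")
  expect_equal(call_presence(q5, broken, 300, require_junction = FALSE)$state,
               "present")
  # intermediate span -> inconclusive
  expect_equal(call_presence(hit(b = 1000L), hit(b = 1150L), 300)$state,
               "inconclusive")
  expect_error(call_presence(q5, q3, 0), "element_length")
})

test_that("self-mapping calls virtually all loci present", {
  sim <- small_sim()
  alu <- sim$repeats[S4Vectors::mcols(sim$repeats)$family == "Alu" &
                       GenomicRanges::width(sim$repeats) >= 280]
  self <- sim$genome
  names(self) <- "self"
  calls <- call_alu_presence(alu, sim$genome, self)
  expect_gte(mean(calls$state == "present"), 0.99)
})

test_that("clade-structured insertions are recovered across species", {
  sim <- small_sim()
  sp <- simulate_species_genomes(sim)
  calls <- call_alu_presence(sp$loci, sim$genome, sp$genomes)
  merged <- merge(calls, sp$truth, by = c("locus_id", "species"),
                  suffixes = c("", "_truth"))
  concl <- merged$state != "inconclusive"
  expect_gte(mean(merged$state[concl] == merged$state_truth[concl]), 0.95)
  cm <- conservation_matrix(calls)
  # no locus excluded upstream appears in the matrix
  fq <- extract_flank_queries(sp$loci, sim$genome)
  expect_true(all(!rownames(cm$matrix) %in% fq$excluded$locus_id))
  # presence decreases with distance from the reference
  d <- stats::cophenetic(sp$tree)["human", ]
  d <- d[names(d) != "human"]
  frac <- cm$species_summary$present_fraction[
    match(names(d), cm$species_summary$species)]
  expect_lt(stats::cor(d, frac, method = "spearman"), 0)
  # a chimp+human insertion is absent in the distant outgroup
  both <- merged[merged$species == "chimp" & merged$state_truth == "present" &
                   merged$state == "present", ]
  expect_gt(nrow(both), 0)
  expect_error(conservation_matrix(rbind(calls, calls[1])), "duplicate")
})

test_that("precomputed blast-style tables can replace the internal aligner", {
  set.seed(64)
  uniq <- random_dna(100)
  q <- Biostrings::DNAStringSet(c(`L9|q5` = uniq))
  hits <- data.table::data.table(
    query_id = "L9|q5", subject = "t", identity_pct = 98, length = 100L,
    mismatch = 2L, gapopen = 0L, qstart = 1L, qend = 100L, sstart = 2001L,
    send = 2100L, evalue = 1e-40, bitscore = 180)
  mq <- map_queries(q, hits = hits)
  expect_true(mq$mapped[1])
  expect_equal(mq$boundary_tpos0[1], 2050L)
  # a close runner-up breaks uniqueness
  hits2 <- rbind(hits, data.table::copy(hits)[, sstart := 5001L][, send := 5100L][, bitscore := 178])
  expect_false(map_queries(q, hits = hits2)$mapped[1])
})
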
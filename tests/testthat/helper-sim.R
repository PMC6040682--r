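# Shared fixtures: small simulations are built once per test run and cached,
# so individual test files stay fast and deterministic.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# small genome with sequence: motif/repeat/footprint tests
small_sim <- function() {
  cached("small_sim", simulate_genome(sim_config(
    seed = 11, genome_length = 4e5, n_peaks = 200, n_opening = 25,
    n_closing = 8, n_genes = 60, peak_width = 300)))
}

small_fragments <- function() {
  cached("small_fragments", simulate_fragments(small_sim()))
}

# coordinates-only simulation at moderate scale: diffacc/linkage tests
count_sim <- function() {
  cached("count_sim", simulate_genome(sim_config(
    seed = 21, genome_length = 4e6, n_peaks = 800, n_opening = 80,
    n_closing = 30, n_genes = 150), sequence = FALSE))
}

count_pipeline <- function() {
  cached("count_pipeline", {
    sim <- count_sim()
    fr <- simulate_fragments(sim)
    cts <- count_fragments(fr$fragments, sim$peaks, samples = fr$samples$sample)
    ranked <- classify_dynamic(rank_peaks(nb_differential(cts, fr$samples$condition)))
    list(sim = sim, fragments = fr, counts = cts, ranked = ranked,
         truth = S4Vectors::mcols(sim$peaks)$state)
  })
}

# brute-force PWM score distribution over all 4^L sequences
enumerate_pwm_scores <- function(pwm) {
  lo <- pwm_logodds(pwm)
  L <- pwm$length
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- rowSums(matrix(lo[cbind(rep(seq_len(L), each = nrow(grid)),
                                    as.vector(grid))], nrow(grid)))
  probs <- apply(grid, 1, function(s) prod(pwm$background[s]))
  list(scores = scores, probs = probs)
}

# smallest score t with P(score >= t) <= alpha, from the enumeration
enumerate_threshold <- function(enum, alpha) {
  o <- order(enum$scores, decreasing = TRUE)
  cum <- cumsum(enum$probs[o])
  ok <- which(cum <= alpha)
  if (!length(ok)) return(max(enum$scores) + 1)
  min(enum$scores[o][seq_len(max(ok))])
}

# brute-force triple-motif join over component hit GRanges: every (E, B, P)
# combination is materialized and filtered with plain vector arithmetic
brute_force_triples <- function(e, b, p, max_span = 50L, gap_range = c(0L, 15L)) {
  dfh <- function(h) data.frame(
    seq = as.character(GenomicRanges::seqnames(h)),
    st = as.character(GenomicRanges::strand(h)),
    s = GenomicRanges::start(h), e = GenomicRanges::end(h))
  de <- dfh(e); db <- dfh(b); dp <- dfh(p)
  combos <- expand.grid(i = seq_len(nrow(de)), j = seq_len(nrow(db)),
                        k = seq_len(nrow(dp)))
  i <- combos$i; j <- combos$j; k <- combos$k
  same <- de$seq[i] == db$seq[j] & db$seq[j] == dp$seq[k] &
          de$st[i] == db$st[j] & db$st[j] == dp$st[k]
  plus <- de$st[i] == "+"
  # strand coordinates (ascending along the strand)
  te1 <- ifelse(plus, de$s[i], -de$e[i]); te2 <- ifelse(plus, de$e[i], -de$s[i])
  tb1 <- ifelse(plus, db$s[j], -db$e[j]); tb2 <- ifelse(plus, db$e[j], -db$s[j])
  tp1 <- ifelse(plus, dp$s[k], -dp$e[k]); tp2 <- ifelse(plus, dp$e[k], -dp$s[k])
  g1 <- tb1 - te2 - 1L
  g2 <- tp1 - tb2 - 1L
  ok <- same & g1 >= gap_range[1] & g1 <= gap_range[2] &
        g2 >= gap_range[1] & g2 <= gap_range[2] &
        (tp2 - te1 + 1L) <= max_span
  sort(sprintf("%s:%s:%d-%d:%d-%d:%d-%d",
               de$seq[i][ok], de$st[i][ok], de$s[i][ok], de$e[i][ok],
               db$s[j][ok], db$e[j][ok], dp$s[k][ok], dp$e[k][ok]))
}

triple_key <- function(hits) {
  if (length(hits) == 0) return(character(0))
  mc <- S4Vectors::mcols(hits)
  sort(sprintf("%s:%s:%d-%d:%d-%d:%d-%d",
               as.character(GenomicRanges::seqnames(hits)),
               as.character(GenomicRanges::strand(hits)),
               mc$esr_start, mc$esr_end, mc$bzip_start, mc$bzip_end,
               mc$pax_start, mc$pax_end))
}

random_pwm <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- matrix(stats::rgamma(L * 4, 0.8), L, 4)
  probs <- probs / rowSums(probs)
  pwm(sprintf("rand%d", L), probs)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
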
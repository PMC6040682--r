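# Transposable-element analyses: family-level overlap enrichment of peaks at
# bp resolution, proportional mapping of genomic positions onto repeat
# consensus coordinates, per-consensus-position overlap/entropy/cut-signal
# profiles across Alu copies, and the 5' vs 3' end asymmetry test.

#' TE family vs peak overlap enrichment
#'
#' For each repeat family, builds the bp-level 2x2 table (peak bp vs non-peak
#' bp, family bp vs not, at 1-bp resolution over the genome) and tests it
#' with a two-sided Fisher exact test (hypergeometric form, usable at genome
#' scale). Also reports the count of peaks overlapping at least one instance
#' and the expected overlap bp from the family's genomic fraction.
#' An optional seeded interval-shuffle gives an empirical expectation.
#'
#' @param peaks peak `GRanges`.
#' @param repeats repeat `GRanges` with `family`.
#' @param genome_length total genome size in bp.
#' @param families families to test (default: all present).
#' @param n_shuffle optional number of random peak placements for an
#'   empirical expected overlap (0 = analytic only).
#' @param seed seed for the shuffle.
#' @return data.frame, one row per family: `family`, `family_bp`,
#'   `overlap_bp`, `expected_bp`, `n_peaks_overlapping`, `odds_ratio`, `p`,
#'   `direction` (+ `shuffle_bp` when shuffled).
#' @export
family_overlap_enrichment <- function(peaks, repeats, genome_length,
                                      families = NULL, n_shuffle = 0L,
                                      seed = 1L) {
  fam_all <- S4Vectors::mcols(repeats)$family
  families <- families %||% sort(unique(fam_all))
  missing <- setdiff(families, fam_all)
  if (length(missing)) {
    warning("family absent from annotation, omitted: ",
            paste(missing, collapse = ", "))
    families <- setdiff(families, missing)
  }
  peaks_red <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
  peak_bp <- as.numeric(sum(GenomicRanges::width(peaks_red)))
  genome_length <- as.numeric(genome_length)
  shuffle_bp <- NULL
  if (n_shuffle > 0) set.seed(seed)
  out <- lapply(families, function(fam) {
    fr <- GenomicRanges::reduce(repeats[fam_all == fam], ignore.strand = TRUE)
    family_bp <- as.numeric(sum(GenomicRanges::width(fr)))
    ov <- GenomicRanges::intersect(peaks_red, fr, ignore.strand = TRUE)
    a <- as.numeric(sum(GenomicRanges::width(ov)))
    b <- peak_bp - a
    c_ <- family_bp - a
    d <- genome_length - peak_bp - family_bp + a
    ft <- fisher_2x2(a, b, c_, d)
    expected <- peak_bp * family_bp / genome_length
    sh <- NA_real_
    if (n_shuffle > 0) {
      w <- GenomicRanges::width(peaks_red)
      sh <- mean(vapply(seq_len(n_shuffle), function(i) {
        st <- sample.int(genome_length - max(w), length(w), replace = TRUE)
        rp <- GenomicRanges::reduce(GenomicRanges::GRanges(
          as.character(GenomicRanges::seqnames(peaks_red))[1],
          IRanges::IRanges(st, width = w)))
        sum(GenomicRanges::width(GenomicRanges::intersect(rp, fr)))
      }, numeric(1)))
    }
    data.frame(family = fam, family_bp = family_bp, overlap_bp = a,
               expected_bp = expected,
               n_peaks_overlapping = sum(IRanges::overlapsAny(peaks, fr,
                                                              ignore.strand = TRUE)),
               odds_ratio = ft$odds_ratio, p = ft$p,
               direction = ifelse(a >= expected, "over", "under"),
               shuffle_bp = sh)
  })
  do.call(rbind, out)
}

#' Map genomic positions to repeat consensus coordinates
#'
#' Strand-aware proportional scaling:
#' `consensus_pos = round(p_along / instance_length * consensus_length)`,
#' where `p_along` runs from the instance's 5' end (minus-strand instances
#' are flipped). Positions are 0-based; `genomic_pos` must lie inside the
#' instance.
#'
#' @param instances repeat `GRanges` (recycled against `genomic_pos`).
#' @param genomic_pos 0-based genomic positions.
#' @return integer consensus positions in `0..consensus_length`.
#' @export
map_to_consensus <- function(instances, genomic_pos) {
  n <- max(length(instances), length(genomic_pos))
  idx <- rep_len(seq_along(instances), n)
  gpos <- rep_len(genomic_pos, n)
  start0 <- GenomicRanges::start(instances)[idx] - 1L
  end0 <- GenomicRanges::end(instances)[idx]
  if (any(gpos < start0 | gpos >= end0)) {
    stop("genomic position outside the repeat instance")
  }
  len <- end0 - start0
  clen <- S4Vectors::mcols(instances)$consensus_length[idx]
  minus <- as.character(GenomicRanges::strand(instances))[idx] == "-"
  p_along <- ifelse(minus, end0 - gpos, gpos - start0)
  as.integer(round(p_along / len * clen))
}

# inverse of the proportional map: genomic 0-based position of consensus
# coordinate `cpos` (may lie in the strand-aware flanks when outside 0..clen)
consensus_to_genomic <- function(instances, cpos) {
  n <- max(length(instances), length(cpos))
  idx <- rep_len(seq_along(instances), n)
  cp <- rep_len(cpos, n)
  start0 <- GenomicRanges::start(instances)[idx] - 1L
  end0 <- GenomicRanges::end(instances)[idx]
  len <- end0 - start0
  clen <- S4Vectors::mcols(instances)$consensus_length[idx]
  minus <- as.character(GenomicRanges::strand(instances))[idx] == "-"
  off <- as.integer(round(cp * len / clen))
  ifelse(minus, end0 - 1L - off, start0 + off)
}

filter_min_len <- function(instances, min_len) {
  keep <- GenomicRanges::width(instances) >= min_len
  if (!any(keep)) stop(sprintf("no instances of length >= %d", min_len))
  instances[keep]
}

#' Per-consensus-position peak overlap frequency
#'
#' For every consensus position (plus `flank` bp of strand-aware surrounding
#' sequence), the fraction of instances whose corresponding genomic base lies
#' inside a peak.
#'
#' @param instances repeat `GRanges` (e.g. Alu copies).
#' @param peaks peak `GRanges`.
#' @param flank flanking consensus positions on each side (default 50).
#' @param min_len minimum instance length (default 300).
#' @return data.frame `position` (consensus coordinate, negative = 5'
#'   flank), `fraction`, `n`.
#' @export
position_overlap_frequency <- function(instances, peaks, flank = 50L,
                                       min_len = 300L) {
  instances <- filter_min_len(instances, min_len)
  clen <- max(S4Vectors::mcols(instances)$consensus_length)
  positions <- seq(-flank, clen + flank)
  n_inst <- length(instances)
  g0 <- consensus_to_genomic(rep(instances, each = length(positions)),
                             rep(positions, times = n_inst))
  G_ok <- g0 >= 0
  qry <- GenomicRanges::GRanges(
    rep(as.character(GenomicRanges::seqnames(instances)), each = length(positions)),
    IRanges::IRanges(pmax(g0, 0) + 1L, width = 1L))
  inpk <- IRanges::overlapsAny(qry, peaks, ignore.strand = TRUE) & G_ok
  mat <- matrix(inpk, nrow = length(positions))
  data.frame(position = positions, fraction = rowMeans(mat), n = n_inst)
}

#' 5' vs 3' end peak-overlap asymmetry
#'
#' Tests whether the strand-aware 3' terminal window of the elements overlaps
#' peaks more often than the 5' terminal window: instances with exactly one
#' overlapping end are informative, and the count of 3'-only instances out
#' of informative ones is tested with a two-sided exact binomial (p = 0.5).
#'
#' @param instances repeat `GRanges`.
#' @param peaks peak `GRanges`.
#' @param end_window terminal window size in bp (default 50).
#' @return list `n_3prime_only`, `n_5prime_only`, `n_informative`, `p`
#'   (NA when nothing is informative), `direction`.
#' @export
end_asymmetry_test <- function(instances, peaks, end_window = 50L) {
  minus <- as.character(GenomicRanges::strand(instances)) == "-"
  s <- GenomicRanges::start(instances)
  e <- GenomicRanges::end(instances)
  w5 <- GenomicRanges::GRanges(GenomicRanges::seqnames(instances),
    IRanges::IRanges(start = ifelse(minus, pmax(e - end_window + 1L, s), s),
                     end = ifelse(minus, e, pmin(s + end_window - 1L, e))))
  w3 <- GenomicRanges::GRanges(GenomicRanges::seqnames(instances),
    IRanges::IRanges(start = ifelse(minus, s, pmax(e - end_window + 1L, s)),
                     end = ifelse(minus, pmin(s + end_window - 1L, e), e)))
  ov5 <- IRanges::overlapsAny(w5, peaks, ignore.strand = TRUE)
  ov3 <- IRanges::overlapsAny(w3, peaks, ignore.strand = TRUE)
  n3 <- sum(ov3 & !ov5)
  n5 <- sum(ov5 & !ov3)
  if (n3 + n5 == 0) {
    return(list(n_3prime_only = 0L, n_5prime_only = 0L, n_informative = 0L,
                p = NA_real_, direction = NA_character_))
  }
  list(n_3prime_only = n3, n_5prime_only = n5, n_informative = n3 + n5,
       p = binom.test(n3, n3 + n5, 0.5)$p.value,
       direction = if (n3 >= n5) "3prime" else "5prime")
}

#' Aligned base-call matrix over consensus positions
#'
#' Extracts, for each instance, the strand-oriented base at every consensus
#' position (plus flanks) via the proportional map; input for
#' [entropy_profile()].
#'
#' @param instances repeat `GRanges`.
#' @param genome named `DNAStringSet`.
#' @param flank consensus flank positions (default 50).
#' @param min_len minimum instance length (default 280).
#' @return character matrix, instances x positions, with a `positions`
#'   attribute; NA outside the genome.
#' @export
consensus_base_matrix <- function(instances, genome, flank = 50L, min_len = 280L) {
  instances <- filter_min_len(instances, min_len)
  clen <- max(S4Vectors::mcols(instances)$consensus_length)
  positions <- seq(-flank, clen + flank)
  chrom <- as.character(GenomicRanges::seqnames(instances))
  minus <- as.character(GenomicRanges::strand(instances)) == "-"
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  mat <- matrix(NA_character_, nrow = length(instances), ncol = length(positions))
  for (i in seq_along(instances)) {
    g0 <- consensus_to_genomic(instances[i], positions)
    glen <- Biostrings::width(genome)[match(chrom[i], names(genome))]
    ok <- g0 >= 0 & g0 < glen
    b <- rep(NA_character_, length(positions))
    if (any(ok)) {
      seqchar <- as.character(Biostrings::subseq(genome[[chrom[i]]],
                                                 min(g0[ok]) + 1L, max(g0[ok]) + 1L))
      chars <- strsplit(seqchar, "")[[1]]
      b[ok] <- chars[g0[ok] - min(g0[ok]) + 1L]
      if (minus[i]) b[ok] <- comp[b[ok]]
    }
    mat[i, ] <- b
  }
  attr(mat, "positions") <- positions
  mat
}

#' Per-position information content in nats
#'
#' For each column of aligned base calls: information = `ln 4 - H`, with
#' `H = -sum f_b ln f_b` over base frequencies computed with a pseudocount
#' of 0.25 per base. High values indicate sequence conservation. Columns
#' with fewer than 10 observations are flagged; empty columns give NA.
#'
#' @param base_mat character matrix of base calls (instances x positions),
#'   e.g. from [consensus_base_matrix()]; non-ACGT entries are ignored.
#' @return data.frame `position`, `info_nats`, `n_obs`, `low_coverage`.
#' @export
entropy_profile <- function(base_mat) {
  positions <- attr(base_mat, "positions") %||% seq_len(ncol(base_mat)) - 1L
  out <- apply(base_mat, 2, function(col) {
    col <- col[col %in% DNA_BASES]
    n <- length(col)
    if (n == 0) return(c(NA_real_, 0))
    f <- (table(factor(col, levels = DNA_BASES)) + 0.25) / (n + 1)
    h <- -sum(f * log(f))
    c(log(4) - h, n)
  })
  data.frame(position = positions, info_nats = out[1, ], n_obs = out[2, ],
             low_coverage = out[2, ] < 10)
}

#' Aggregate cut profile in consensus coordinates
#'
#' Strand-specific Tn5 cut counts mapped onto the repeat consensus (plus
#' `flank` bp of surrounding sequence) via the proportional map, oriented by
#' instance strand (cut strand labels swap on minus-strand instances), and
#' averaged over instances.
#'
#' @param cuts data.table from [fragments_to_cuts()].
#' @param instances repeat `GRanges`.
#' @param flank surrounding consensus positions (default 50).
#' @param min_len minimum instance length (default 300).
#' @return a `cut_profile` whose `offset` is the consensus position
#'   (negative = 5' flank).
#' @export
aggregate_cut_profile_over_elements <- function(cuts, instances, flank = 50L,
                                                min_len = 300L) {
  instances <- filter_min_len(instances, min_len)
  clen <- max(S4Vectors::mcols(instances)$consensus_length)
  npos <- clen + 2L * flank + 1L
  plus <- numeric(npos)
  minus_v <- numeric(npos)
  # genomic flank in bp scales with instance length
  s0 <- GenomicRanges::start(instances) - 1L
  e0 <- GenomicRanges::end(instances)
  len <- e0 - s0
  gflank <- as.integer(ceiling(flank * len / S4Vectors::mcols(instances)$consensus_length))
  ext <- GenomicRanges::GRanges(GenomicRanges::seqnames(instances),
                                IRanges::IRanges(s0 - gflank + 1L, e0 + gflank))
  cutgr <- GenomicRanges::GRanges(cuts$chrom, IRanges::IRanges(cuts$pos + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(cutgr, ext, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (length(qi)) {
    gpos <- cuts$pos[qi]
    inst_minus <- as.character(GenomicRanges::strand(instances))[si] == "-"
    p_along <- ifelse(inst_minus, e0[si] - 1L - gpos, gpos - s0[si])
    cpos <- as.integer(round(p_along / len[si] * S4Vectors::mcols(instances)$consensus_length[si]))
    idx <- cpos + flank + 1L
    ok <- idx >= 1L & idx <= npos
    cstrand <- cuts$strand[qi]
    oriented_plus <- ifelse(inst_minus, cstrand == "-", cstrand == "+")
    plus <- tabulate(idx[ok & oriented_plus], nbins = npos)
    minus_v <- tabulate(idx[ok & !oriented_plus], nbins = npos)
  }
  structure(list(
    offset = seq(-flank, clen + flank),
    plus = plus / length(instances),
    minus = minus_v / length(instances),
    n_sites = length(instances),
    motif_width = as.integer(clen),
    window = npos), class = "cut_profile")
}
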
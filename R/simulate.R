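# Synthetic-data generator: every input the pipeline consumes, with planted
# ground truth. The generator emulates the statistical structure the analysis
# assumes -- two-condition negative-binomial fragment counts with planted
# opening/closing peaks, Tn5 cut profiles with protected motif cores and
# strand-asymmetric flanking excess, Alu-like repeats carrying an
# ESR -> bZIP -> Pax triple motif in their 3' half, several TE families, a
# clade-structured set of "primate" genomes with lineage-specific Alu
# insertions, and an expression table coupled to peak dynamics.

# Synthetic stand-in binding-site consensus strings (not database PWMs).
ESR_SITE <- "GGTCACAGTGACC"
BZIP_SITE <- "TGACTCA"
PAX_SITE <- "GTCACGCTTGA"

#' Synthetic Alu-like consensus (300 bp)
#'
#' A fixed 300-bp synthetic consensus whose 3' half carries the ordered
#' ESR, bZIP and Pax-like binding sites (positions 201-241, 1-based; gaps of
#' 5 bp; span 41 bp) and ends in a 12-bp poly-A stretch, mimicking the
#' geometry of the triple motif at the 3' end of genuine Alu elements. The
#' backbone is arbitrary fixed sequence; this is a synthetic stand-in, not
#' the Alu consensus from RepBase.
#' @export
alu_consensus_synthetic <- function() {
  paste0(
    "CCACGTGAGGTGCATCCATTCACCATTCTCGCTGACAACGTTACTCCGCGTTTGAGGAATGCGTCAACGA",
    "AAATAGATTATATGGTAAATGAACCGTTGGGAATCCGGTAGCGTTTATGCTTTTGTCCAGCGGCCTCAGG",
    "AATGGCACAAGTGTGGAAAGCTGATATTAAGTTTTACTGGCCTAGGCGAAAGAAAATAGG",
    ESR_SITE, "CTCTA", BZIP_SITE, "TCTAA", PAX_SITE,
    "TGTATCTTTCTATCTCTAAATATACCACTTATAATTAATCTAATAGA",
    "AAAAAAAAAAAA"
  )
}

# 1-based positions of the protected triple-motif core within the consensus
ALU_TRIPLE_CORE <- c(201L, 241L)

#' Synthetic component PWMs for the triple motif
#'
#' Sharp synthetic stand-ins for the ESR, bZIP and Pax-domain motifs (the
#' published analysis used database PWMs, which are not shipped here).
#' @param p_consensus per-position probability of the consensus base.
#' @return named list of three [pwm()] objects.
#' @export
synthetic_pwms <- function(p_consensus = 0.85) {
  list(
    esr = pwm_from_consensus("esr_like", ESR_SITE, p_consensus),
    bzip = pwm_from_consensus("bzip_like", BZIP_SITE, p_consensus),
    pax = pwm_from_consensus("pax_like", PAX_SITE, p_consensus)
  )
}

# per-family instance-length samplers and consensus lengths
TE_FAMILY_SPECS <- list(
  Alu = list(consensus_length = 300L),
  L1 = list(consensus_length = 6000L, len_range = c(500L, 3000L)),
  CR1 = list(consensus_length = 4500L, len_range = c(300L, 1500L)),
  ERVL = list(consensus_length = 2400L, len_range = c(300L, 1000L)),
  ERVK = list(consensus_length = 3000L, len_range = c(300L, 1000L)),
  `hAT-Charlie` = list(consensus_length = 600L, len_range = c(200L, 600L)),
  Satellite = list(consensus_length = 2000L, len_range = c(300L, 2000L)),
  Low_complexity = list(consensus_length = 300L, len_range = c(50L, 300L)),
  Simple_repeat = list(consensus_length = 150L, len_range = c(30L, 150L))
)

#' Simulation configuration
#'
#' Defaults define the study conditions every planted-truth test runs under:
#' 5000 peaks of which 200 open and 50 close with a log2 effect of 2 between
#' 3+3 replicates, negative-binomial dispersion 0.05, 80% footprint
#' protection inside occupied motifs, an Alu-like family at ~5% of the
#' genome, and a five-species clade tree with the reference in the ingroup.
#'
#' @param seed master seed; all stages derive their streams from it.
#' @param genome_length simulated chromosome length in bp (>= 100 kb for
#'   [simulate_genome()]).
#' @param chrom chromosome name.
#' @param n_genes,n_peaks,n_opening,n_closing feature counts.
#' @param effect_log2fc planted accessibility log2 fold change (decidualized
#'   vs control); 0 means no dynamic peaks are planted at all.
#' @param nb_dispersion NB dispersion alpha in `var = mu + alpha * mu^2`.
#' @param base_mean median expected fragments per peak per sample.
#' @param n_replicates_per_condition replicates per condition (>= 1).
#' @param peak_width planted peak width (bp).
#' @param frac_peaks_tss fraction of peaks centered within 10 kb upstream of
#'   a TSS; `frac_peaks_alu3` fraction centered on Alu 3' ends;
#'   `frac_peaks_motif` fraction carrying a planted bZIP site at their
#'   center, of which `frac_motif_occupied` are occupied (footprinted).
#' @param motif_opening_bias sampling weight favouring opening peaks when
#'   choosing which peaks carry a motif site (1 = unbiased).
#' @param te_family_weights named genomic bp fractions per TE family
#'   (must sum to <= 1).
#' @param alu_consensus Alu-like consensus sequence carrying the triple motif
#'   in its 3' half.
#' @param alu_divergence per-copy substitution fraction outside the protected
#'   triple-motif core.
#' @param footprint_protection fraction of Tn5 cuts suppressed inside
#'   occupied motif cores (in \[0, 1)).
#' @param footprint_excess rate of extra motif-spanning fragments per
#'   occupied site (fraction of the peak's fragment count), producing the
#'   plus-strand 5' / minus-strand 3' flanking excess.
#' @param fragment_length_range uniform fragment length bounds (bp).
#' @param background_frac off-peak fragments as a fraction of in-peak ones.
#' @param species_tree newick string; `reference_species` must be a tip.
#' @param substitution_rate per-bp substitutions per unit branch length.
#' @param expression_effect,expression_sd mean |log2fc| of genes linked to
#'   dynamic peaks, and the Gaussian noise around it.
#' @param gc_block,gc_range background GC varies per block of this size,
#'   uniformly within `gc_range` (gives the GC/CpG matcher structure).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e7L,
                       chrom = "chrSim",
                       n_genes = 300L,
                       n_peaks = 5000L,
                       n_opening = 200L,
                       n_closing = 50L,
                       effect_log2fc = 2,
                       nb_dispersion = 0.05,
                       base_mean = 100,
                       n_replicates_per_condition = 3L,
                       peak_width = 400L,
                       frac_peaks_tss = 0.3,
                       frac_peaks_alu3 = 0.1,
                       frac_peaks_motif = 0.4,
                       frac_motif_occupied = 0.5,
                       motif_opening_bias = 6,
                       te_family_weights = c(Alu = 0.05, L1 = 0.04, CR1 = 0.01,
                                             ERVL = 0.01, ERVK = 0.005,
                                             `hAT-Charlie` = 0.01,
                                             Satellite = 0.005,
                                             Low_complexity = 0.005,
                                             Simple_repeat = 0.005),
                       alu_consensus = alu_consensus_synthetic(),
                       alu_divergence = 0.08,
                       footprint_protection = 0.8,
                       footprint_excess = 0.25,
                       fragment_length_range = c(60L, 120L),
                       background_frac = 0.15,
                       species_tree = paste0(
                         "((((chimp:0.08,human:0.08):0.12,rhesus:0.3):0.25,",
                         "(squirrel_monkey:0.35,marmoset:0.35):0.3):0.15,",
                         "galago:0.9);"),
                       reference_species = "human",
                       substitution_rate = 0.05,
                       expression_effect = 1.0,
                       expression_sd = 0.5,
                       gc_block = 10000L,
                       gc_range = c(0.4, 0.6)) {
  cfg <- as.list(environment())
  if (any(te_family_weights < 0) || sum(te_family_weights) > 1) {
    stop("te_family_weights must be non-negative and sum to <= 1")
  }
  if (sum(te_family_weights) * genome_length > 0.8 * genome_length) {
    stop("requested repeat bp cannot be packed into the genome")
  }
  counts <- c(n_genes, n_peaks, n_opening, n_closing)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (n_opening + n_closing > n_peaks) stop("more dynamic peaks than peaks")
  if (footprint_protection < 0 || footprint_protection >= 1) {
    stop("footprint_protection must be in [0, 1)")
  }
  if (n_replicates_per_condition < 1) stop("zero replicates per condition")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  stopifnot(nchar(alu_consensus) >= 100)
  class(cfg) <- "sim_config"
  cfg
}

#' Read / write a simulation config as a YAML key/value file
#' @rdname sim_config
#' @export
write_sim_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("the 'yaml' package is required")
  x <- unclass(config)
  x$te_family_weights <- as.list(x$te_family_weights)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname sim_config
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("the 'yaml' package is required")
  x <- yaml::read_yaml(path)
  x$te_family_weights <- unlist(x$te_family_weights)
  do.call(sim_config, x)
}

# mutate integer base codes (1..4) at per-base probability p, excluding
# positions in `protect` (logical or index vector)
mutate_codes <- function(code, p, protect = NULL) {
  if (p <= 0) return(code)
  hit <- which(runif(length(code)) < p)
  if (!is.null(protect)) hit <- setdiff(hit, protect)
  if (length(hit)) {
    code[hit] <- ((code[hit] - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L) + 1L
  }
  code
}

codes_to_dna <- function(code) {
  intToUtf8(c(65L, 67L, 71L, 84L)[code])
}

dna_to_codes <- function(x) encode_dna(x)

revcomp_codes <- function(code) rev(5L - code)

# place intervals of given widths uniformly without overlap (against each
# other and against `avoid`); returns start positions (1-based) or NA for
# widths that could not be placed
place_nonoverlapping <- function(widths, genome_length, avoid = NULL,
                                 margin = 200L, max_pass = 60L) {
  n <- length(widths)
  starts <- rep(NA_integer_, n)
  taken <- avoid %||% IRanges::IRanges()
  todo <- seq_len(n)
  for (pass in seq_len(max_pass)) {
    if (!length(todo)) break
    cand <- vapply(widths[todo], function(w) {
      hi <- genome_length - w - margin
      if (hi <= margin) NA_integer_ else margin + sample.int(hi - margin, 1L)
    }, integer(1))
    okw <- !is.na(cand)
    ir <- IRanges::IRanges(cand[okw], width = widths[todo][okw])
    free <- !IRanges::overlapsAny(ir, taken)
    # also reject overlaps within this batch (keep first of each clash)
    self <- GenomicRanges::findOverlaps(ir, ir)
    clash <- unique(S4Vectors::subjectHits(self)[S4Vectors::queryHits(self) < S4Vectors::subjectHits(self)])
    free[clash] <- FALSE
    acc <- todo[okw][free]
    starts[acc] <- cand[okw][free]
    taken <- c(taken, ir[free])
    todo <- todo[is.na(starts[todo])]
  }
  starts
}

#' Simulate the reference genome with planted features
#'
#' Plants non-overlapping TE instances at the configured family fractions
#' (every Alu copy carries the triple motif in its 3' half, protected from
#' per-copy divergence), gene TSSs with simple exon models, peaks (a
#' configurable fraction centered on Alu 3' ends or upstream of TSSs) with
#' planted opening/closing states, and bZIP motif sites at peak centers for
#' footprint analysis. With `sequence = FALSE` only coordinates and truth
#' tables are produced (enough for the count-based analyses).
#'
#' @param config a [sim_config()].
#' @param sequence generate the genome sequence (default TRUE).
#' @return a `stromatac_sim` list: `config`, `genome` (`DNAStringSet` or
#'   NULL), `peaks`, `repeats`, `genes`, `exons`, `motif_sites` (GRanges with
#'   truth metadata), and `truth` (data.tables keyed by feature id).
#' @export
simulate_genome <- function(config, sequence = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length < 1e5) stop("genome_length must be >= 100 kb")
  set.seed(child_seed(config$seed, 1L))
  G <- as.integer(config$genome_length)
  chrom <- config$chrom
  clen_alu <- nchar(config$alu_consensus)

  # --- TE instances ---
  te <- list()
  for (fam in names(config$te_family_weights)) {
    target <- config$te_family_weights[[fam]] * G
    if (target <= 0) next
    spec <- TE_FAMILY_SPECS[[fam]] %||% list(consensus_length = 1000L,
                                             len_range = c(200L, 1000L))
    lens <- integer(0)
    while (sum(lens) < target) {
      if (fam == "Alu") {
        # truncations keep the 3' end; the floor keeps the triple-motif core
        # inside the instance's 3' half even for truncated copies
        l <- if (runif(1) < 0.85) clen_alu else sample(170:280, 1L)
      } else {
        l <- sample(spec$len_range[1]:spec$len_range[2], 1L)
      }
      lens <- c(lens, l)
    }
    sub <- if (fam == "Alu") sample(c("AluJ", "AluS", "AluY"), length(lens),
                                    replace = TRUE, prob = c(0.25, 0.45, 0.3))
           else paste0(fam, "-1")
    te[[fam]] <- data.table::data.table(
      family = fam, subfamily = sub, len = lens,
      consensus_length = if (fam == "Alu") clen_alu else spec$consensus_length,
      strand = sample(c("+", "-"), length(lens), replace = TRUE))
  }
  te <- data.table::rbindlist(te)
  te_start <- place_nonoverlapping(te$len, G)
  te <- te[!is.na(te_start)]
  te_start <- te_start[!is.na(te_start)]
  repeats <- granges_from_bed0(rep(chrom, nrow(te)), te_start - 1L,
                               te_start - 1L + te$len,
                               strand = te$strand, family = te$family,
                               subfamily = te$subfamily,
                               consensus_length = te$consensus_length)
  S4Vectors::mcols(repeats)$name <- sprintf("rep%05d", seq_len(nrow(te)))

  # genomic interval of the planted triple motif per Alu copy (truncated Alus
  # keep the 3' end of the consensus, so the core is present whenever the
  # instance is long enough to reach back to it)
  is_alu <- te$family == "Alu"
  trip <- data.table::data.table(gstart = rep(NA_integer_, nrow(te)),
                                 gend = rep(NA_integer_, nrow(te)))
  core0 <- ALU_TRIPLE_CORE[1] - 1L   # 0-based core start in consensus
  core1 <- ALU_TRIPLE_CORE[2]        # 0-based exclusive end
  for (i in which(is_alu)) {
    off <- clen_alu - te$len[i]      # 5'-truncation offset
    if (core0 < off) next
    if (te$strand[i] == "+") {
      trip$gstart[i] <- te_start[i] - 1L + (core0 - off)
      trip$gend[i] <- te_start[i] - 1L + (core1 - off)
    } else {
      trip$gend[i] <- te_start[i] - 1L + te$len[i] - (core0 - off)
      trip$gstart[i] <- te_start[i] - 1L + te$len[i] - (core1 - off)
    }
  }
  S4Vectors::mcols(repeats)$triple_gstart <- trip$gstart
  S4Vectors::mcols(repeats)$triple_gend <- trip$gend

  # --- genes ---
  n_genes <- config$n_genes
  tss_pos <- sort(sample.int(G - 60000L, n_genes) + 5000L)
  gstrand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- granges_from_bed0(rep(chrom, n_genes), tss_pos, tss_pos + 1L,
                             strand = gstrand,
                             gene_id = sprintf("g%04d", seq_len(n_genes)))
  exons <- list()
  for (i in seq_len(n_genes)) {
    body_len <- sample(5000:30000, 1L)
    n_ex <- sample(3:7, 1L)
    offs <- sort(sample.int(body_len - 200L, n_ex - 1L))
    estarts0 <- c(0L, offs)
    dirn <- if (gstrand[i] == "+") 1L else -1L
    es <- tss_pos[i] + dirn * estarts0
    if (dirn == -1L) es <- es - 150L
    es <- pmax(0L, pmin(es, G - 151L))
    exons[[i]] <- data.table::data.table(start0 = es, end0 = es + 150L,
                                         gene_id = sprintf("g%04d", i),
                                         strand = gstrand[i])
  }
  exons <- data.table::rbindlist(exons)
  exons_gr <- granges_from_bed0(rep(chrom, nrow(exons)), exons$start0,
                                exons$end0, strand = exons$strand,
                                gene_id = exons$gene_id)

  # --- peaks ---
  np <- config$n_peaks
  pw <- as.integer(config$peak_width)
  n_alu3 <- round(config$frac_peaks_alu3 * np)
  n_tss <- round(config$frac_peaks_tss * np)
  centers <- integer(0)
  origin <- character(0)
  full_alu <- which(is_alu & te$len >= 280L)
  if (n_alu3 > 0 && length(full_alu)) {
    pick <- sample(full_alu, min(n_alu3, length(full_alu)))
    ac <- ifelse(te$strand[pick] == "+",
                 te_start[pick] - 1L + te$len[pick] - 30L,
                 te_start[pick] - 1L + 30L)
    centers <- c(centers, ac)
    origin <- c(origin, rep("alu3", length(ac)))
  }
  if (n_tss > 0) {
    gi <- sample.int(n_genes, n_tss, replace = TRUE)
    d <- sample(500:9500, n_tss, replace = TRUE)
    tc <- ifelse(gstrand[gi] == "+", tss_pos[gi] - d, tss_pos[gi] + d)
    centers <- c(centers, tc)
    origin <- c(origin, rep("tss", n_tss))
  }
  n_rand <- np - length(centers)
  centers <- c(centers, sample.int(G - 2L * pw, n_rand) + pw)
  origin <- c(origin, rep("random", n_rand))
  pstart0 <- pmax(0L, pmin(as.integer(centers) - pw %/% 2L, G - pw))
  # de-overlap: keep first of each overlapping clique, replace the rest
  ir <- IRanges::IRanges(pstart0 + 1L, width = pw)
  keep <- !logical(np)
  ov <- GenomicRanges::findOverlaps(ir, ir)
  keep[unique(S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)])] <- FALSE
  n_replace <- sum(!keep)
  if (n_replace > 0) {
    rs <- place_nonoverlapping(rep(pw, n_replace), G, avoid = ir[keep])
    pstart0[!keep] <- rs - 1L
    origin[!keep] <- "random"
    drop <- is.na(pstart0)
    pstart0 <- pstart0[!drop]; origin <- origin[!drop]
  }
  np <- length(pstart0)
  peaks <- granges_from_bed0(rep(chrom, np), pstart0, pstart0 + pw,
                             name = sprintf("p%05d", seq_len(np)),
                             origin = origin)
  state <- rep("unchanged", np)
  if (config$effect_log2fc != 0 && (config$n_opening + config$n_closing) > 0) {
    dyn <- sample.int(np, min(np, config$n_opening + config$n_closing))
    state[dyn[seq_len(min(config$n_opening, length(dyn)))]] <- "opening"
    if (config$n_closing > 0 && length(dyn) > config$n_opening) {
      state[dyn[(config$n_opening + 1L):length(dyn)]] <- "closing"
    }
  }
  S4Vectors::mcols(peaks)$state <- state
  S4Vectors::mcols(peaks)$base_mean <-
    stats::rlnorm(np, meanlog = log(config$base_mean), sdlog = 0.5)

  # --- planted bZIP motif sites at peak centers ---
  # opening peaks are favoured (motif-driven opening), so motif frequency
  # decreases along the accessibility ranking as in real dynamic chromatin
  n_motif <- round(config$frac_peaks_motif * np)
  w <- ifelse(state == "opening", config$motif_opening_bias, 1)
  w[origin == "alu3"] <- 0   # never overwrite a planted Alu triple core
  mpk <- sample.int(np, n_motif, prob = w)
  msw <- nchar(BZIP_SITE)
  mcent <- pstart0[mpk] + pw %/% 2L
  mstart0 <- mcent - msw %/% 2L
  motif_sites <- granges_from_bed0(rep(chrom, n_motif), mstart0, mstart0 + msw,
                                   strand = sample(c("+", "-"), n_motif, TRUE),
                                   peak = sprintf("p%05d", mpk),
                                   occupied = runif(n_motif) < config$frac_motif_occupied,
                                   motif = rep("bzip_like", n_motif))

  # --- sequence assembly ---
  genome <- NULL
  if (sequence) {
    nblock <- ceiling(G / config$gc_block)
    gc <- runif(nblock, config$gc_range[1], config$gc_range[2])
    code <- integer(G)
    for (bi in seq_len(nblock)) {
      i0 <- (bi - 1L) * config$gc_block + 1L
      i1 <- min(G, bi * config$gc_block)
      p <- c((1 - gc[bi]) / 2, gc[bi] / 2, gc[bi] / 2, (1 - gc[bi]) / 2)
      code[i0:i1] <- sample.int(4L, i1 - i0 + 1L, replace = TRUE, prob = p)
    }
    alu_code <- dna_to_codes(config$alu_consensus)
    fam_cons <- lapply(names(TE_FAMILY_SPECS), function(fam) {
      sample.int(4L, TE_FAMILY_SPECS[[fam]]$consensus_length, replace = TRUE)
    })
    names(fam_cons) <- names(TE_FAMILY_SPECS)
    for (i in seq_len(nrow(te))) {
      len <- te$len[i]
      if (is_alu[i]) {
        off <- clen_alu - len
        inst <- alu_code[(off + 1L):clen_alu]
        prot <- which((off + seq_len(len)) >= ALU_TRIPLE_CORE[1] &
                      (off + seq_len(len)) <= ALU_TRIPLE_CORE[2])
        inst <- mutate_codes(inst, config$alu_divergence, protect = prot)
      } else {
        cons <- fam_cons[[te$family[i]]] %||% sample.int(4L, len, replace = TRUE)
        inst <- cons[seq_len(min(len, length(cons)))]
        if (length(inst) < len) inst <- rep_len(inst, len)
        inst <- mutate_codes(inst, 0.10)
      }
      if (te$strand[i] == "-") inst <- revcomp_codes(inst)
      code[te_start[i]:(te_start[i] + len - 1L)] <- inst
    }
    bz <- dna_to_codes(BZIP_SITE)
    for (i in seq_len(n_motif)) {
      inst <- bz
      if (as.character(GenomicRanges::strand(motif_sites))[i] == "-") {
        inst <- revcomp_codes(inst)
      }
      code[(mstart0[i] + 1L):(mstart0[i] + msw)] <- inst
    }
    genome <- Biostrings::DNAStringSet(setNames(codes_to_dna(code), chrom))
  }

  truth_peaks <- data.table::data.table(
    id = S4Vectors::mcols(peaks)$name,
    chrom = chrom, start = pstart0, end = pstart0 + pw,
    state = state, base_mean = S4Vectors::mcols(peaks)$base_mean,
    origin = origin)

  structure(list(config = config, genome = genome, peaks = peaks,
                 repeats = repeats, genes = genes, exons = exons_gr,
                 motif_sites = motif_sites,
                 truth = list(peaks = truth_peaks)),
            class = "stromatac_sim")
}

#' Simulate per-sample ATAC fragments
#'
#' Per-peak fragment counts are negative binomial (`var = mu + alpha mu^2`)
#' with the planted effect applied to the decidualized condition of dynamic
#' peaks. Fragments inside occupied motif sites are thinned: each Tn5 cut
#' falling in an occupied core survives with probability
#' `1 - footprint_protection`. Each occupied site additionally attracts
#' motif-spanning fragments whose cuts land immediately 5' (plus strand) and
#' 3' (minus strand) of the core, reproducing the footprint flanking-excess
#' geometry. Off-peak background fragments are scattered uniformly.
#'
#' @param sim a [simulate_genome()] result.
#' @return list with `fragments` (data.table `chrom,start,end,sample`,
#'   0-based half-open) and `samples` (data.table `sample`, `condition`).
#' @export
simulate_fragments <- function(sim) {
  config <- sim$config
  set.seed(child_seed(config$seed, 2L))
  n_rep <- config$n_replicates_per_condition
  samples <- data.table::data.table(
    sample = c(sprintf("ctrl_%d", seq_len(n_rep)), sprintf("dec_%d", seq_len(n_rep))),
    condition = rep(c("ctrl", "dec"), each = n_rep))
  peaks <- sim$peaks
  np <- length(peaks)
  pstart0 <- GenomicRanges::start(peaks) - 1L
  pend0 <- GenomicRanges::end(peaks)
  pw <- pend0 - pstart0
  state <- S4Vectors::mcols(peaks)$state
  base <- S4Vectors::mcols(peaks)$base_mean
  flr <- config$fragment_length_range
  G <- config$genome_length
  chrom <- config$chrom
  occ <- sim$motif_sites[S4Vectors::mcols(sim$motif_sites)$occupied]
  occ_start0 <- GenomicRanges::start(occ) - 1L
  occ_end0 <- GenomicRanges::end(occ)
  # peak index containing each occupied site
  occ_peak <- GenomicRanges::findOverlaps(occ, peaks, select = "first")
  depth <- stats::rlnorm(nrow(samples), 0, 0.1)
  out <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    eff <- ifelse(state == "opening", config$effect_log2fc,
                  ifelse(state == "closing", -config$effect_log2fc, 0))
    mu <- base * depth[s] * (if (samples$condition[s] == "dec") 2^eff else 1)
    k <- if (config$nb_dispersion > 0) {
      rnbinom(np, mu = mu, size = 1 / config$nb_dispersion)
    } else rpois(np, mu)
    pk <- rep.int(seq_len(np), k)
    n <- length(pk)
    len <- sample(flr[1]:flr[2], n, replace = TRUE)
    mid <- pstart0[pk] + floor(runif(n) * pw[pk])
    fs <- pmax(0L, as.integer(mid - len %/% 2L))
    fe <- pmin(G, fs + len)
    # footprint thinning on cut positions inside occupied cores
    if (length(occ) && config$footprint_protection > 0) {
      cut_p <- fs + 4L
      cut_m <- fe - 5L
      in_core <- function(pos) {
        iv <- IRanges::IRanges(pos + 1L, width = 1L)
        IRanges::overlapsAny(iv, IRanges::IRanges(occ_start0 + 1L, occ_end0))
      }
      hits <- in_core(cut_p) + in_core(cut_m)
      keep <- runif(n) < (1 - config$footprint_protection)^hits
      fs <- fs[keep]; fe <- fe[keep]
    }
    # motif-spanning excess fragments at occupied sites
    if (length(occ) && config$footprint_excess > 0) {
      nex <- rpois(length(occ), config$footprint_excess * ifelse(is.na(occ_peak), 0, k[occ_peak]))
      si <- rep.int(seq_along(occ), nex)
      m <- length(si)
      if (m > 0) {
        d1 <- sample(3:25, m, replace = TRUE)
        d2 <- sample(3:25, m, replace = TRUE)
        xs <- pmax(0L, occ_start0[si] - 4L - d1)
        xe <- pmin(G, occ_end0[si] + 5L + d2)
        fs <- c(fs, xs); fe <- c(fe, xe)
      }
    }
    # background fragments
    nbg <- round(config$background_frac * length(fs))
    if (nbg > 0) {
      bl <- sample(flr[1]:flr[2], nbg, replace = TRUE)
      bs <- sample.int(G - max(flr) - 1L, nbg, replace = TRUE)
      fs <- c(fs, bs); fe <- c(fe, bs + bl)
    }
    out[[s]] <- data.table::data.table(chrom = chrom, start = fs, end = fe,
                                       sample = samples$sample[s])
  }
  list(fragments = data.table::rbindlist(out), samples = samples)
}

#' Simulate species genomes with lineage-specific Alu insertions
#'
#' Conservation loci are the planted Alu copies of at least `min_len` bp.
#' Each locus is assigned an origin edge on the path from the root to the
#' reference tip (probability proportional to branch length): species in the
#' clade below that edge carry the insertion, others do not. Every
#' non-reference genome is the reference sequence with absent loci spliced
#' out and substitutions applied at
#' `p = substitution_rate * patristic distance` to the reference.
#'
#' @param sim a [simulate_genome()] result (needs the sequence).
#' @param min_len minimum Alu instance length to track as a locus.
#' @return list with `genomes` (named `DNAStringSet`, non-reference tips),
#'   `loci` (reference-coordinate `GRanges` of tracked Alu copies), `truth`
#'   (data.table `locus_id`, `species`, `state`), and `tree` (ape phylo).
#' @export
simulate_species_genomes <- function(sim, min_len = 280L) {
  config <- sim$config
  if (is.null(sim$genome)) stop("simulate_genome() must be run with sequence = TRUE")
  set.seed(child_seed(config$seed, 3L))
  tree <- ape::read.tree(text = config$species_tree)
  ref <- config$reference_species
  if (!ref %in% tree$tip.label) stop("reference_species not a tip of species_tree")
  alu <- sim$repeats[S4Vectors::mcols(sim$repeats)$family == "Alu" &
                       GenomicRanges::width(sim$repeats) >= min_len]
  S4Vectors::mcols(alu)$locus_id <- S4Vectors::mcols(alu)$name
  n_loc <- length(alu)
  # edges on the root -> reference path
  ref_tip <- match(ref, tree$tip.label)
  path_edges <- integer(0)
  node <- ref_tip
  root <- ape::Ntip(tree) + 1L
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    path_edges <- c(path_edges, e)
    node <- tree$edge[e, 1]
  }
  elen <- tree$edge.length[path_edges]
  origin_edge <- sample(path_edges, n_loc, replace = TRUE, prob = elen)
  tip_desc <- lapply(seq_along(path_edges), function(i) {
    ch <- tree$edge[path_edges[i], 2]
    if (ch <= ape::Ntip(tree)) tree$tip.label[ch]
    else tree$tip.label[phangorn_desc(tree, ch)]
  })
  names(tip_desc) <- as.character(path_edges)
  species <- setdiff(tree$tip.label, ref)
  dmat <- stats::cophenetic(tree)
  code0 <- dna_to_codes(as.character(sim$genome[[1]]))
  truth <- list()
  genomes <- vector("list", length(species))
  names(genomes) <- species
  locus_start0 <- GenomicRanges::start(alu) - 1L
  locus_end0 <- GenomicRanges::end(alu)
  for (sp in species) {
    present <- vapply(seq_len(n_loc), function(i) {
      sp %in% tip_desc[[as.character(origin_edge[i])]]
    }, logical(1))
    keep <- rep(TRUE, length(code0))
    for (i in which(!present)) {
      keep[(locus_start0[i] + 1L):locus_end0[i]] <- FALSE
    }
    p_sub <- min(0.75, config$substitution_rate * dmat[ref, sp])
    codes <- mutate_codes(code0[keep], p_sub)
    genomes[[sp]] <- codes_to_dna(codes)
    truth[[sp]] <- data.table::data.table(
      locus_id = S4Vectors::mcols(alu)$locus_id, species = sp,
      state = ifelse(present, "present", "absent"))
  }
  genomes <- Biostrings::DNAStringSet(unlist(genomes))
  names(genomes) <- species
  list(genomes = genomes, loci = alu,
       truth = data.table::rbindlist(truth), tree = tree)
}

# descendant tips of an internal node (small trees; simple recursion)
phangorn_desc <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' Simulate a differential-expression table coupled to peak dynamics
#'
#' Genes linked (within `max_dist` of their TSS) to a planted opening peak
#' get mean `+expression_effect`, to a closing peak `-expression_effect`
#' (opening wins if both), all others 0, plus Gaussian noise.
#'
#' @param sim a [simulate_genome()] result.
#' @param max_dist linking distance in bp.
#' @return data.table `gene_id`, `log2fc`, `truth_group`.
#' @export
simulate_expression <- function(sim, max_dist = 10000L) {
  config <- sim$config
  set.seed(child_seed(config$seed, 4L))
  links <- link_peaks_to_genes(sim$peaks, sim$genes, max_dist = max_dist)
  state <- setNames(S4Vectors::mcols(sim$peaks)$state,
                    S4Vectors::mcols(sim$peaks)$name)
  gid <- S4Vectors::mcols(sim$genes)$gene_id
  grp <- rep("background", length(gid))
  if (nrow(links)) {
    st <- state[links$peak_id]
    open_genes <- unique(links$gene_id[st == "opening"])
    close_genes <- setdiff(unique(links$gene_id[st == "closing"]), open_genes)
    grp[gid %in% open_genes] <- "opening"
    grp[gid %in% close_genes] <- "closing"
  }
  eff <- ifelse(grp == "opening", config$expression_effect,
                ifelse(grp == "closing", -config$expression_effect, 0))
  data.table::data.table(
    gene_id = gid,
    log2fc = eff + rnorm(length(gid), 0, config$expression_sd),
    truth_group = grp)
}

#' Write all simulated inputs to a directory in their on-disk formats
#'
#' Emits `genome.fa`, `peaks.narrowPeak`, `genes.bed`, `repeats.out`,
#' `fragments_<sample>.tsv`, `expression.tsv`, `config.yaml` and the
#' ground-truth tables (`truth_*.tsv`), so the pipeline can be exercised
#' from files alone.
#' @param sim a [simulate_genome()] result.
#' @param dir output directory (created).
#' @param fragments optional [simulate_fragments()] result to write.
#' @param expression optional [simulate_expression()] table.
#' @export
write_sim <- function(sim, dir, fragments = NULL, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$genome)) write_fasta(sim$genome, file.path(dir, "genome.fa"))
  pk <- sim$peaks
  S4Vectors::mcols(pk)$score <- 0
  write_bed(pk, file.path(dir, "peaks.narrowPeak"), "narrowPeak")
  g <- sim$genes
  S4Vectors::mcols(g)$name <- S4Vectors::mcols(g)$gene_id
  write_bed(g, file.path(dir, "genes.bed"), "bed6")
  write_repeatmasker_out(sim$repeats, file.path(dir, "repeats.out"))
  data.table::fwrite(sim$truth$peaks, file.path(dir, "truth_peaks.tsv"), sep = "\t")
  if (!is.null(fragments)) {
    for (s in fragments$samples$sample) {
      write_fragments(fragments$fragments[fragments$fragments$sample == s],
                      file.path(dir, sprintf("fragments_%s.tsv", s)))
    }
    data.table::fwrite(fragments$samples, file.path(dir, "samples.tsv"), sep = "\t")
  }
  if (!is.null(expression)) {
    data.table::fwrite(expression, file.path(dir, "expression.tsv"), sep = "\t")
  }
  if (requireNamespace("yaml", quietly = TRUE)) {
    write_sim_config(sim$config, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
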
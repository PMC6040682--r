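# Motif scanning and enrichment: genome-wide PWM scans against the calibrated
# score distribution, GC/CpG-matched background sampling near TSSs, Fisher
# enrichment of motif-bearing peaks, and the ESR -> bZIP -> Pax triple-motif
# scanner.

encode_dna <- function(x) {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(as.character(x))]
}

# integer windowed PWM scores on the calibration grid; NA where the window
# contains a non-ACGT base
pwm_window_scores <- function(code, kmat) {
  n <- length(code)
  L <- nrow(kmat)
  if (n < L) return(integer(0))
  m <- n - L + 1L
  sc <- integer(m)
  ok <- rep(TRUE, m)
  for (l in seq_len(L)) {
    idx <- code[l:(l + m - 1L)]
    nas <- is.na(idx)
    if (any(nas)) {
      ok <- ok & !nas
      idx[nas] <- 1L
    }
    sc <- sc + kmat[l, idx]
  }
  sc[!ok] <- NA_integer_
  sc
}

#' Extract interval sequences from an in-memory genome
#'
#' @param genome a named `DNAStringSet`.
#' @param gr intervals (`GRanges`); minus-strand intervals are
#'   reverse-complemented.
#' @export
extract_interval_seqs <- function(genome, gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  stopifnot(all(chrom %in% names(genome)))
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]],
                                    start = GenomicRanges::start(gr)[i],
                                    end = GenomicRanges::end(gr)[i]))
  }, character(1)))
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  if (any(minus)) out[minus] <- Biostrings::reverseComplement(out[minus])
  names(out) <- if (!is.null(S4Vectors::mcols(gr)$name)) S4Vectors::mcols(gr)$name else
    sprintf("%s:%d-%d", chrom, GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  out
}

#' Scan sequences with a calibrated PWM
#'
#' Both strands are scanned; a hit is reported at every offset whose score
#' (discretized on the calibration grid, so scan and threshold are mutually
#' consistent) reaches the calibration threshold. Minus-strand hits are
#' scored with the reverse-complemented matrix at the same coordinates.
#'
#' @param seqs a `DNAStringSet` (or single `DNAString`/character).
#' @param calib a [pwm_score_threshold()] calibration.
#' @param threshold optional override of the calibrated threshold (bits).
#' @param both_strands scan the minus strand too (default TRUE).
#' @return `GRanges` of hits with `motif`, `score` (bits) and `pvalue`
#'   metadata; sequences shorter than the PWM yield no hits.
#' @export
scan_pwm <- function(seqs, calib, threshold = NULL, both_strands = TRUE) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is(seqs, "DNAString")) seqs <- Biostrings::DNAStringSet(list(seqs))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  g <- calib$granularity
  kmat <- t(round(pwm_logodds(calib$pwm) / g))   # 4 x L for fast row lookup
  L <- calib$pwm$length
  kthr <- as.integer(round((threshold %||% calib$threshold) / g))
  koff <- as.integer(round(calib$score_grid[1] / g))
  krc <- kmat[4:1, rev(seq_len(L)), drop = FALSE]
  res <- vector("list", 2L * length(seqs))
  for (i in seq_along(seqs)) {
    code <- encode_dna(seqs[[i]])
    for (st in c("+", if (both_strands) "-")) {
      km <- if (st == "+") kmat else krc
      sc <- pwm_window_scores(code, t(km))
      hit <- which(!is.na(sc) & sc >= kthr)
      if (!length(hit)) next
      res[[2L * (i - 1L) + (st == "-") + 1L]] <- GenomicRanges::GRanges(
        seqnames = names(seqs)[i],
        ranges = IRanges::IRanges(start = hit, width = L),
        strand = st,
        motif = calib$pwm$name,
        score = sc[hit] * g,
        pvalue = calib$survival[pmin(pmax(sc[hit] - koff + 1L, 1L),
                                     length(calib$survival))]
      )
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(GenomicRanges::GRanges(motif = character(), score = numeric(),
                                  pvalue = numeric()))
  }
  # hits from different sequences carry different seqlevels by construction
  out <- suppressWarnings(do.call(c, res))
  sort(out, ignore.strand = TRUE)
}

# ---- GC/CpG-matched background sampling --------------------------------------

#' GC fraction of sequences
#' @export
gc_content <- function(seqs) {
  as.numeric(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))
}

#' CpG observed/expected ratio
#'
#' The standard definition `(#CG dinucleotides * length) / (#C * #G)`;
#' 0 when the sequence has no C or no G.
#' @export
cpg_oe <- function(seqs) {
  din <- Biostrings::dinucleotideFrequency(seqs)[, "CG"]
  mono <- Biostrings::letterFrequency(seqs, c("C", "G"))
  len <- Biostrings::width(seqs)
  denom <- mono[, "C"] * mono[, "G"]
  ifelse(denom > 0, din * len / denom, 0)
}

#' Sample GC/CpG-matched background intervals near TSSs
#'
#' For each input peak, draws an interval of the same width within
#' `tss_flank` of a random TSS whose GC fraction falls in the same
#' `gc_bin_width` bin and whose CpG observed/expected falls in the same
#' `cpg_bin_width` bin. Sampling is without replacement (no interval reused).
#' If no candidate matches after `max_tries` draws, the nearest candidate is
#' used and a warning records the fallback.
#'
#' @param peaks input intervals (`GRanges`).
#' @param genome named `DNAStringSet`.
#' @param tss width-1 `GRanges` of transcription starts.
#' @param n_per_input background intervals per input peak.
#' @param seed RNG seed (sampling is fully seeded).
#' @param tss_flank maximum distance from a TSS (default 50 kb).
#' @param gc_bin_width,cpg_bin_width matching bin widths (0.05 / 0.1).
#' @param max_tries candidate draws per background interval before fallback.
#' @return `GRanges` of background intervals with `matched_peak`, `gc`,
#'   `cpg_oe` metadata.
#' @export
sample_matched_background <- function(peaks, genome, tss, n_per_input = 1L,
                                      seed = 1L, tss_flank = 50000L,
                                      gc_bin_width = 0.05, cpg_bin_width = 0.1,
                                      max_tries = 1000L) {
  stopifnot(length(peaks) > 0, length(tss) > 0)
  set.seed(seed)
  peak_seqs <- extract_interval_seqs(genome, peaks)
  gc_in <- gc_content(peak_seqs)
  cpg_in <- cpg_oe(peak_seqs)
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  tss_chr <- as.character(GenomicRanges::seqnames(tss))
  tss_pos <- GenomicRanges::start(tss)
  used <- new.env(parent = emptyenv())
  n_fallback <- 0L
  batch <- 128L
  out_chr <- character(0); out_start <- integer(0); out_peak <- integer(0)
  out_gc <- numeric(0); out_cpg <- numeric(0)
  draw_batch <- function(w, n) {
    j <- sample.int(length(tss), n, replace = TRUE)
    lo <- pmax(1L, tss_pos[j] - tss_flank)
    hi <- pmin(chrom_len[tss_chr[j]] - w + 1L, tss_pos[j] + tss_flank - w + 1L)
    ok <- hi >= lo
    j <- j[ok]; lo <- lo[ok]; hi <- hi[ok]
    s <- as.integer(lo + floor(runif(length(j)) * (hi - lo + 1L)))
    chr <- tss_chr[j]
    seqs <- Biostrings::DNAStringSet(rep("", length(j)))
    for (ctg in unique(chr)) {
      sel <- chr == ctg
      seqs[sel] <- Biostrings::extractAt(genome[[ctg]],
                                         IRanges::IRanges(s[sel], width = w))
    }
    list(chr = chr, s = s, gc = gc_content(seqs), cpg = cpg_oe(seqs))
  }
  for (i in seq_along(peaks)) {
    w <- GenomicRanges::width(peaks)[i]
    gbin <- floor(gc_in[i] / gc_bin_width)
    cbin <- floor(cpg_in[i] / cpg_bin_width)
    for (r in seq_len(n_per_input)) {
      best <- NULL
      best_d <- Inf
      found <- FALSE
      tries <- 0L
      while (tries < max_tries && !found) {
        cand <- draw_batch(w, min(batch, max_tries - tries))
        tries <- tries + batch
        keys <- paste0(cand$chr, ":", cand$s, "-", w)
        fresh <- vapply(keys, function(kk) is.null(used[[kk]]), logical(1))
        hit <- which(fresh & floor(cand$gc / gc_bin_width) == gbin &
                       floor(cand$cpg / cpg_bin_width) == cbin)
        if (length(hit)) {
          h <- hit[1]
          used[[keys[h]]] <- TRUE
          found <- TRUE
        } else {
          d <- abs(cand$gc - gc_in[i]) / gc_bin_width +
               abs(cand$cpg - cpg_in[i]) / cpg_bin_width
          d[!fresh] <- Inf
          h <- which.min(d)
          if (length(h) && d[h] < best_d) {
            best_d <- d[h]
            best <- list(chr = cand$chr[h], s = cand$s[h], gc = cand$gc[h],
                         cpg = cand$cpg[h], key = keys[h])
          }
          h <- NULL
        }
        if (found) {
          out_chr <- c(out_chr, cand$chr[hit[1]])
          out_start <- c(out_start, cand$s[hit[1]])
          out_peak <- c(out_peak, i)
          out_gc <- c(out_gc, cand$gc[hit[1]])
          out_cpg <- c(out_cpg, cand$cpg[hit[1]])
        }
      }
      if (!found) {
        if (is.null(best)) stop("no placeable background candidate near any TSS")
        n_fallback <- n_fallback + 1L
        used[[best$key]] <- TRUE
        out_chr <- c(out_chr, best$chr)
        out_start <- c(out_start, best$s)
        out_peak <- c(out_peak, i)
        out_gc <- c(out_gc, best$gc)
        out_cpg <- c(out_cpg, best$cpg)
      }
    }
  }
  if (n_fallback > 0) {
    warning(sprintf("%d background interval(s) fell back to the nearest GC/CpG bin",
                    n_fallback))
  }
  widths <- GenomicRanges::width(peaks)[out_peak]
  res <- GenomicRanges::GRanges(out_chr, IRanges::IRanges(out_start, width = widths),
                                matched_peak = out_peak, gc = out_gc,
                                cpg_oe = out_cpg)
  S4Vectors::mcols(res)$fallback_count <- n_fallback
  res
}

# ---- enrichment --------------------------------------------------------------

#' Motif enrichment of target vs background peaks
#'
#' A peak "features" the motif if it has at least one hit. The 2x2 table of
#' motif-bearing vs motif-free peaks in target and background sets is tested
#' with a two-sided Fisher exact test; the reported odds ratio is the sample
#' odds ratio `(a*d)/(b*c)`.
#'
#' @param target,background either `DNAStringSet`s of peak sequences or
#'   `GRanges` (then `genome` is required).
#' @param calib a [pwm_score_threshold()] calibration.
#' @param genome named `DNAStringSet`, needed when intervals are supplied.
#' @return list with `target_frac`, `background_frac` (percent scale in
#'   `target_pct`/`background_pct`), `odds_ratio`, `p`, and the 2x2 `table`.
#' @export
motif_enrichment <- function(target, background, calib, genome = NULL) {
  as_seqs <- function(x, label) {
    if (is(x, "GRanges")) {
      if (is.null(genome)) stop("genome required when ", label, " is a GRanges")
      x <- extract_interval_seqs(genome, x)
    }
    names(x) <- sprintf("s%d", seq_along(x))
    x
  }
  tg <- as_seqs(target, "target")
  bg <- as_seqs(background, "background")
  if (length(tg) == 0) stop("empty target set")
  n_with <- function(seqs) {
    hits <- scan_pwm(seqs, calib)
    length(unique(as.character(GenomicRanges::seqnames(hits))))
  }
  a <- n_with(tg); b <- length(tg) - a
  c_ <- n_with(bg); d <- length(bg) - c_
  ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
  list(
    target_frac = a / length(tg), background_frac = c_ / length(bg),
    target_pct = 100 * a / length(tg), background_pct = 100 * c_ / length(bg),
    odds_ratio = (a * d) / (b * c_), p = ft$p.value,
    table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
                   dimnames = list(c("target", "background"),
                                   c("with_motif", "without")))
  )
}

# ---- triple motif ------------------------------------------------------------

#' Find ordered ESR -> bZIP -> Pax triple motifs
#'
#' Reports every same-strand arrangement in which the three component hits
#' occur in ESR, bZIP, Pax order along the strand, each inter-hit gap lies in
#' `gap_range` (bp between consecutive hits, 0 = abutting) and the total span
#' is at most `max_span`. Overlapping arrangements are each reported; output
#' is sorted by sequence, start, strand.
#'
#' @param seqs `DNAStringSet` to scan.
#' @param calib_esr,calib_bzip,calib_pax component calibrations from
#'   [pwm_score_threshold()].
#' @param max_span maximum spanning width in bp (default 50).
#' @param gap_range length-2 inclusive bounds on each inter-hit gap.
#' @return `GRanges` spanning each arrangement, with component coordinates
#'   (`esr_start` ... `pax_end`, 1-based on the scanned sequence) and scores
#'   in the metadata.
#' @export
find_triple_motif <- function(seqs, calib_esr, calib_bzip, calib_pax,
                              max_span = 50L, gap_range = c(0L, 15L)) {
  min_span <- calib_esr$pwm$length + calib_bzip$pwm$length + calib_pax$pwm$length
  if (max_span < min_span) {
    stop(sprintf("max_span (%d) < total PWM length (%d)", max_span, min_span))
  }
  hits <- list(esr = scan_pwm(seqs, calib_esr),
               bzip = scan_pwm(seqs, calib_bzip),
               pax = scan_pwm(seqs, calib_pax))
  combine_hits(hits$esr, hits$bzip, hits$pax, max_span = max_span,
               gap_range = gap_range)
}

#' Combine pre-computed component hits into triple-motif arrangements
#'
#' Exposed separately so pre-scanned hit sets can be joined (and so tests can
#' compare against a brute-force join).
#' @rdname find_triple_motif
#' @param esr_hits,bzip_hits,pax_hits component hit `GRanges` from
#'   [scan_pwm()].
#' @export
combine_hits <- function(esr_hits, bzip_hits, pax_hits, max_span = 50L,
                         gap_range = c(0L, 15L)) {
  out <- list()
  keys <- unique(c(
    paste(as.character(GenomicRanges::seqnames(esr_hits)),
          as.character(GenomicRanges::strand(esr_hits)))))
  for (key in keys) {
    seqn <- sub(" [+-]$", "", key)
    st <- sub("^.* ", "", key)
    sel <- function(h) {
      h[as.character(GenomicRanges::seqnames(h)) == seqn &
          as.character(GenomicRanges::strand(h)) == st]
    }
    e <- sel(esr_hits); b <- sel(bzip_hits); p <- sel(pax_hits)
    if (!length(e) || !length(b) || !length(p)) next
    # strand coordinates: ascending along the hit strand
    tr <- function(h) {
      if (st == "+") cbind(GenomicRanges::start(h), GenomicRanges::end(h))
      else cbind(-GenomicRanges::end(h), -GenomicRanges::start(h))
    }
    te <- tr(e); tb <- tr(b); tp <- tr(p)
    ob <- order(tb[, 1]); tb <- tb[ob, , drop = FALSE]; b <- b[ob]
    op <- order(tp[, 1]); tp <- tp[op, , drop = FALSE]; p <- p[op]
    for (i in seq_along(e)) {
      jb <- which(tb[, 1] >= te[i, 2] + 1 + gap_range[1] &
                  tb[, 1] <= te[i, 2] + 1 + gap_range[2])
      for (j in jb) {
        jp <- which(tp[, 1] >= tb[j, 2] + 1 + gap_range[1] &
                    tp[, 1] <= tb[j, 2] + 1 + gap_range[2] &
                    tp[, 2] - te[i, 1] + 1 <= max_span)
        for (kk in jp) {
          gstart <- min(GenomicRanges::start(e)[i], GenomicRanges::start(b)[j],
                        GenomicRanges::start(p)[kk])
          gend <- max(GenomicRanges::end(e)[i], GenomicRanges::end(b)[j],
                      GenomicRanges::end(p)[kk])
          out[[length(out) + 1L]] <- data.table::data.table(
            seqnames = seqn, start = gstart, end = gend, strand = st,
            esr_start = GenomicRanges::start(e)[i], esr_end = GenomicRanges::end(e)[i],
            bzip_start = GenomicRanges::start(b)[j], bzip_end = GenomicRanges::end(b)[j],
            pax_start = GenomicRanges::start(p)[kk], pax_end = GenomicRanges::end(p)[kk],
            esr_score = S4Vectors::mcols(e)$score[i],
            bzip_score = S4Vectors::mcols(b)$score[j],
            pax_score = S4Vectors::mcols(p)$score[kk])
        }
      }
    }
  }
  if (!length(out)) {
    return(GenomicRanges::GRanges(esr_start = integer(), esr_end = integer(),
                                  bzip_start = integer(), bzip_end = integer(),
                                  pax_start = integer(), pax_end = integer(),
                                  esr_score = numeric(), bzip_score = numeric(),
                                  pax_score = numeric()))
  }
  dt <- data.table::rbindlist(out)
  data.table::setorder(dt, seqnames, start, strand)
  GenomicRanges::GRanges(
    seqnames = dt$seqnames, ranges = IRanges::IRanges(dt$start, dt$end),
    strand = dt$strand,
    esr_start = dt$esr_start, esr_end = dt$esr_end,
    bzip_start = dt$bzip_start, bzip_end = dt$bzip_end,
    pax_start = dt$pax_start, pax_end = dt$pax_end,
    esr_score = dt$esr_score, bzip_score = dt$bzip_score,
    pax_score = dt$pax_score)
}

#' Assign triple-motif hits to repeat instances
#'
#' Each hit is assigned to the repeat containing its midpoint (`"none"` when
#' the midpoint lies outside every repeat). Whether the hit lies in the
#' element's 3' half is determined strand-aware from the repeat instance:
#' for a minus-strand element the genomic left half is its 3' half.
#'
#' @param hits triple-motif `GRanges` from [find_triple_motif()].
#' @param repeats repeat `GRanges` with a `family` metadata column.
#' @return list with `per_hit` (data.table: family, three_prime per hit),
#'   `family_counts`, and `alu_three_prime_fraction` (fraction of all hits
#'   whose midpoint lies in the 3' half of an Alu copy).
#' @export
triple_motif_repeat_overlap <- function(hits, repeats) {
  if (length(hits) == 0) {
    return(list(per_hit = data.table::data.table(family = character(),
                                                 three_prime = logical()),
                family_counts = table(character()),
                alu_three_prime_fraction = NA_real_))
  }
  mid <- floor((GenomicRanges::start(hits) + GenomicRanges::end(hits)) / 2)
  midgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(hits),
                                  IRanges::IRanges(mid, width = 1L))
  ov <- GenomicRanges::findOverlaps(midgr, repeats, select = "first",
                                    ignore.strand = TRUE)
  fam <- rep("none", length(hits))
  three <- rep(NA, length(hits))
  inrep <- !is.na(ov)
  if (any(inrep)) {
    ri <- ov[inrep]
    fam[inrep] <- S4Vectors::mcols(repeats)$family[ri]
    rs <- GenomicRanges::start(repeats)[ri]
    re <- GenomicRanges::end(repeats)[ri]
    rw <- re - rs + 1L
    rstrand <- as.character(GenomicRanges::strand(repeats))[ri]
    pos_along <- ifelse(rstrand == "-", re - mid[inrep], mid[inrep] - rs)
    three[inrep] <- pos_along >= rw / 2
  }
  per_hit <- data.table::data.table(family = fam, three_prime = three)
  list(
    per_hit = per_hit,
    family_counts = table(fam),
    alu_three_prime_fraction = mean(fam == "Alu" & !is.na(three) & three)
  )
}
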
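# Cross-species Alu presence/absence calling: 100-bp junction-spanning flank
# queries, an internal seed-and-extend mapper (exact k-mer seeds, ungapped
# extension), projection of the element boundaries through each flank
# alignment, and the presence/absence decision rule.

#' Extract junction-spanning flank queries for repeat instances
#'
#' For each instance, two `flank_len`-bp queries centered on the element
#' boundaries: `q5` spans the 5' junction (outer flank first, element head
#' last) and `q3` the 3' junction (element tail first, outer flank last),
#' both read 5'->3' along the element (minus-strand instances are
#' reverse-complemented). Instances too close to a contig edge are excluded
#' and reported.
#'
#' @param instances repeat `GRanges` with a `name` column (locus ids).
#' @param genome named `DNAStringSet`.
#' @param flank_len query length (default 100; half outside, half inside).
#' @return list: `queries` (named `DNAStringSet`, `<locus>|q5` and
#'   `<locus>|q3`), `info` (data.table `locus_id`, `element_length`),
#'   `excluded` (data.table `locus_id`, `reason`).
#' @export
extract_flank_queries <- function(instances, genome, flank_len = 100L) {
  half <- flank_len %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(instances))
  glen <- setNames(Biostrings::width(genome), names(genome))[chrom]
  s0 <- GenomicRanges::start(instances) - 1L
  e0 <- GenomicRanges::end(instances)
  minus <- as.character(GenomicRanges::strand(instances)) == "-"
  ids <- S4Vectors::mcols(instances)$name %||% sprintf("locus%05d", seq_along(instances))
  ok <- s0 - half >= 0 & e0 + half <= glen
  excluded <- data.table::data.table(locus_id = ids[!ok],
                                     reason = "within flank_len/2 of contig edge")
  qs <- character(0)
  qn <- character(0)
  info <- data.table::data.table(locus_id = character(), element_length = integer())
  for (i in which(ok)) {
    left <- as.character(Biostrings::subseq(genome[[chrom[i]]], s0[i] - half + 1L, s0[i] + half))
    right <- as.character(Biostrings::subseq(genome[[chrom[i]]], e0[i] - half + 1L, e0[i] + half))
    if (!minus[i]) {
      q5 <- left; q3 <- right
    } else {
      q5 <- reverse_complement_chr(right)
      q3 <- reverse_complement_chr(left)
    }
    qs <- c(qs, q5, q3)
    qn <- c(qn, paste0(ids[i], "|q5"), paste0(ids[i], "|q3"))
    info <- rbind(info, data.table::data.table(locus_id = ids[i],
                                               element_length = e0[i] - s0[i]))
  }
  queries <- Biostrings::DNAStringSet(qs)
  names(queries) <- qn
  list(queries = queries, info = info, excluded = excluded)
}

# ungapped comparison of a query (integer codes) against the target at a
# fixed diagonal; returns per-position match indicator (FALSE off the target)
diagonal_matches <- function(qcode, tcode, tstart1) {
  L <- length(qcode)
  idx <- tstart1:(tstart1 + L - 1L)
  ok <- idx >= 1L & idx <= length(tcode)
  m <- logical(L)
  m[ok] <- qcode[ok] == tcode[idx[ok]]
  m
}

# best ungapped segment by Kadane on +1 match / -2 mismatch scores
best_segment <- function(m, match_score = 1, mismatch_score = -2) {
  v <- ifelse(m, match_score, mismatch_score)
  best <- 0; cur <- 0; cs <- 1L; bs <- 0L; be <- -1L
  for (i in seq_along(v)) {
    if (cur <= 0) { cur <- v[i]; cs <- i } else cur <- cur + v[i]
    if (cur > best) { best <- cur; bs <- cs; be <- i }
  }
  if (be < bs) return(list(score = 0, start = 0L, end = -1L, len = 0L, identity = 0))
  len <- be - bs + 1L
  list(score = best, start = bs, end = be, len = len,
       identity = mean(m[bs:be]))
}

#' Map flank queries to a target genome (internal seed-and-extend aligner)
#'
#' Exact `k`-mer seeds (both strands) vote for alignment diagonals; each
#' candidate diagonal is scored by ungapped comparison (+1 match / -2
#' mismatch) and its best segment must reach `min_identity` over at least
#' `min_seg_len` bp. Nearby candidates are clustered and a query is
#' "mapped" only when the best cluster's score exceeds the runner-up by at
#' least `unique_margin` (the uniqueness rule). Alternatively supply
#' pre-computed blast-style tabular `hits` (see [read_alignment_hits()]).
#'
#' @param queries named `DNAStringSet` from [extract_flank_queries()].
#' @param target named `DNAStringSet` target genome (one or more contigs).
#' @param hits optional pre-computed alignment table used instead of
#'   `target`.
#' @param k seed length (default 13).
#' @param min_identity identity floor of the best segment (default 0.8).
#' @param min_seg_len minimum best-segment length in bp (default 40, so the
#'   50-bp outer flank half of an absent element can still map).
#' @param unique_margin best minus second-best score margin (default 5).
#' @param max_candidates diagonals evaluated per query and strand.
#' @return data.table, one row per query: `query_id`, `mapped`, `subject`,
#'   `orientation`, `score`, `margin`, `boundary_tpos0` (0-based target
#'   position aligned to the query midpoint, the projected element
#'   boundary), `id_first50`, `id_last50` (identity of the query halves on
#'   the winning diagonal, in original query orientation).
#' @export
map_queries <- function(queries, target = NULL, hits = NULL, k = 13L,
                        min_identity = 0.8, min_seg_len = 40L,
                        unique_margin = 5, max_candidates = 50L) {
  if (is.null(target) && is.null(hits)) {
    stop("supply either a target genome or a precomputed hits table")
  }
  if (!is.null(hits)) return(map_queries_from_hits(queries, hits, unique_margin))
  L <- unique(Biostrings::width(queries))
  stopifnot(length(L) == 1)
  half <- L %/% 2L
  nq <- length(queries)
  qchars <- lapply(seq_len(nq), function(i) encode_dna(queries[[i]]))
  # candidate diagonals from exact k-mer seeds, per strand
  cands <- list()
  for (ori in c("+", "-")) {
    qset <- if (ori == "+") queries else Biostrings::reverseComplement(queries)
    offs <- seq_len(L - k + 1L)
    pat <- Biostrings::DNAStringSet(unlist(lapply(seq_len(nq), function(i) {
      substring(as.character(qset[[i]]), offs, offs + k - 1L)
    })))
    keep <- !grepl("[^ACGT]", as.character(pat))
    pat_q <- rep(seq_len(nq), each = length(offs))[keep]
    pat_o <- rep(offs, times = nq)[keep]
    pd <- Biostrings::PDict(pat[keep])
    for (ctg in names(target)) {
      mi <- Biostrings::matchPDict(pd, target[[ctg]])
      nh <- S4Vectors::elementNROWS(mi)
      if (!sum(nh)) next
      st <- unlist(Biostrings::startIndex(mi)[nh > 0], use.names = FALSE)
      pid <- rep.int(which(nh > 0), nh[nh > 0])
      dt <- data.table::data.table(q = pat_q[pid],
                                   diag = st - pat_o[pid] + 1L)
      dt <- dt[, .N, by = c("q", "diag")]
      dt$subject <- ctg
      dt$orientation <- ori
      cands[[length(cands) + 1L]] <- dt
    }
  }
  out <- data.table::data.table(
    query_id = names(queries), mapped = FALSE, subject = NA_character_,
    orientation = NA_character_, score = NA_real_, margin = NA_real_,
    boundary_tpos0 = NA_integer_, id_first50 = NA_real_, id_last50 = NA_real_)
  if (!length(cands)) return(out)
  cands <- data.table::rbindlist(cands)
  tcodes <- lapply(names(target), function(ctg) encode_dna(target[[ctg]]))
  names(tcodes) <- names(target)
  rc_qchars <- lapply(seq_len(nq), function(i) revcomp_codes(qchars[[i]]))
  for (qi in seq_len(nq)) {
    cq <- cands[cands$q == qi]
    if (!nrow(cq)) next
    data.table::setorder(cq, -N)
    cq <- head(cq, max_candidates)
    evals <- lapply(seq_len(nrow(cq)), function(r) {
      qc <- if (cq$orientation[r] == "+") qchars[[qi]] else rc_qchars[[qi]]
      m <- diagonal_matches(qc, tcodes[[cq$subject[r]]], cq$diag[r])
      seg <- best_segment(m)
      list(m = m, seg = seg, row = r)
    })
    valid <- vapply(evals, function(e) {
      e$seg$len >= min_seg_len && e$seg$identity >= min_identity
    }, logical(1))
    evals <- evals[valid]
    if (!length(evals)) next
    sc <- vapply(evals, function(e) e$seg$score, numeric(1))
    dgs <- cq$diag[vapply(evals, `[[`, integer(1), "row")]
    sbj <- cq$subject[vapply(evals, `[[`, integer(1), "row")]
    ori <- cq$orientation[vapply(evals, `[[`, integer(1), "row")]
    # cluster candidates within 20 bp on the same contig/strand
    cl <- integer(length(evals))
    ncl <- 0L
    for (i in order(-sc)) {
      if (cl[i] > 0) next
      ncl <- ncl + 1L
      same <- which(sbj == sbj[i] & ori == ori[i] & abs(dgs - dgs[i]) <= 20L & cl == 0L)
      cl[same] <- ncl
    }
    cl_best <- vapply(split(sc, cl), max, numeric(1))
    best_cl <- as.integer(names(cl_best))[which.max(cl_best)]
    best_score <- max(cl_best)
    second <- if (length(cl_best) > 1) sort(cl_best, decreasing = TRUE)[2] else -Inf
    margin <- best_score - second
    i_best <- which(cl == best_cl)[which.max(sc[cl == best_cl])]
    e <- evals[[i_best]]
    m <- e$m
    o <- ori[i_best]
    d <- dgs[i_best]
    if (o == "+") {
      id_first <- mean(m[1:half]); id_last <- mean(m[(half + 1L):L])
      boundary <- (d - 1L) + half          # 0-based target pos of query offset `half`
    } else {
      # reverse-complement alignment: original position j sits at rc position L+1-j
      id_first <- mean(m[(half + 1L):L]); id_last <- mean(m[1:half])
      boundary <- (d - 1L) + (L - half)    # 0-based target pos aligned to the midpoint
    }
    data.table::set(out, qi, "mapped", margin >= unique_margin)
    data.table::set(out, qi, "subject", sbj[i_best])
    data.table::set(out, qi, "orientation", o)
    data.table::set(out, qi, "score", best_score)
    data.table::set(out, qi, "margin", as.numeric(margin))
    data.table::set(out, qi, "boundary_tpos0", as.integer(boundary))
    data.table::set(out, qi, "id_first50", id_first)
    data.table::set(out, qi, "id_last50", id_last)
  }
  out
}

# best-unique-hit selection from a precomputed blast-style table
map_queries_from_hits <- function(queries, hits, unique_margin = 5) {
  half <- unique(Biostrings::width(queries)) %/% 2L
  out <- data.table::data.table(
    query_id = names(queries), mapped = FALSE, subject = NA_character_,
    orientation = NA_character_, score = NA_real_, margin = NA_real_,
    boundary_tpos0 = NA_integer_, id_first50 = NA_real_, id_last50 = NA_real_)
  for (qi in seq_along(queries)) {
    h <- hits[hits$query_id == names(queries)[qi]]
    if (!nrow(h)) next
    data.table::setorder(h, -bitscore)
    margin <- if (nrow(h) > 1) h$bitscore[1] - h$bitscore[2] else Inf
    ori <- if (h$send[1] >= h$sstart[1]) "+" else "-"
    # project the query midpoint through the (assumed ungapped) alignment
    boundary <- if (ori == "+") h$sstart[1] - 1L + (half - (h$qstart[1] - 1L))
                else (h$sstart[1] - 1L) - (half - (h$qstart[1] - 1L))
    idp <- h$identity_pct[1] / 100
    data.table::set(out, qi, "mapped", margin >= unique_margin)
    data.table::set(out, qi, "subject", h$subject[1])
    data.table::set(out, qi, "orientation", ori)
    data.table::set(out, qi, "score", h$bitscore[1])
    data.table::set(out, qi, "margin", as.numeric(margin))
    data.table::set(out, qi, "boundary_tpos0", as.integer(boundary))
    data.table::set(out, qi, "id_first50", idp)
    data.table::set(out, qi, "id_last50", idp)
  }
  out
}

#' Presence/absence call for one locus in one species
#'
#' Decision rule: if either flank query is unmapped, or the two map to
#' different contigs or orientations, or anti-colinearly, the locus is
#' `inconclusive`. Otherwise `D` is the inferred element span: the distance
#' between the element boundaries projected through the two flank
#' alignments. The locus is `present` when `|D - element_length| <=
#' span_tol * element_length` and (when `require_junction`) both junction
#' halves (the inner 50 bp of each query) align at `>= junction_min`
#' identity; `absent` when `D <= adjacent_max` bp (the flanks are nearly
#' adjacent, the element is missing); anything else is `inconclusive`.
#'
#' @param hit5,hit3 single rows of a [map_queries()] table for the locus's
#'   q5 and q3 queries.
#' @param element_length reference element length in bp (> 0).
#' @param span_tol fractional tolerance on the element span (default 0.3).
#' @param adjacent_max maximum span called absent (default 60 bp).
#' @param junction_min junction identity floor for presence (default 0.6).
#' @param require_junction require junction support for `present`
#'   (default TRUE).
#' @return list `state` and `evidence` (named logicals: `flank5_mapped`,
#'   `flank3_mapped`, `colinear`, `junction_support`).
#' @export
call_presence <- function(hit5, hit3, element_length, span_tol = 0.3,
                          adjacent_max = 60L, junction_min = 0.6,
                          require_junction = TRUE) {
  if (element_length <= 0) stop("element_length must be > 0")
  ev <- c(flank5_mapped = isTRUE(hit5$mapped), flank3_mapped = isTRUE(hit3$mapped),
          colinear = FALSE, junction_support = FALSE)
  if (!ev[["flank5_mapped"]] || !ev[["flank3_mapped"]]) {
    return(list(state = "inconclusive", evidence = ev))
  }
  if (hit5$subject != hit3$subject || hit5$orientation != hit3$orientation) {
    return(list(state = "inconclusive", evidence = ev))
  }
  D <- if (hit5$orientation == "+") hit3$boundary_tpos0 - hit5$boundary_tpos0
       else hit5$boundary_tpos0 - hit3$boundary_tpos0
  if (D < -30) return(list(state = "inconclusive", evidence = ev))
  ev[["colinear"]] <- TRUE
  # junction halves: element side of each query (q5: last 50, q3: first 50)
  ev[["junction_support"]] <- hit5$id_last50 >= junction_min &&
    hit3$id_first50 >= junction_min
  if (abs(D - element_length) <= span_tol * element_length &&
      (!require_junction || ev[["junction_support"]])) {
    return(list(state = "present", evidence = ev))
  }
  if (D <= adjacent_max) return(list(state = "absent", evidence = ev))
  list(state = "inconclusive", evidence = ev)
}

#' Presence/absence calling of repeat loci across species genomes
#'
#' Runs [extract_flank_queries()] once against the reference, maps the
#' queries to every target genome with [map_queries()], and applies
#' [call_presence()] per locus and species.
#'
#' @param instances repeat `GRanges` (loci to track, `name` = locus id).
#' @param ref_genome reference `DNAStringSet`.
#' @param target_genomes `DNAStringSet`, one contig per species, names =
#'   species labels (or a named list of `DNAStringSet`s).
#' @param flank_len flank query length (default 100).
#' @param ... tuning parameters forwarded to [map_queries()] and
#'   [call_presence()].
#' @return data.table of calls: `locus_id`, `species`, `state`, evidence
#'   columns.
#' @export
call_alu_presence <- function(instances, ref_genome, target_genomes,
                              flank_len = 100L, k = 13L, min_identity = 0.8,
                              min_seg_len = 40L, unique_margin = 5,
                              span_tol = 0.3, adjacent_max = 60L,
                              junction_min = 0.6, require_junction = TRUE) {
  fq <- extract_flank_queries(instances, ref_genome, flank_len)
  if (!is.list(target_genomes) || is(target_genomes, "DNAStringSet")) {
    tg <- lapply(seq_along(target_genomes), function(i) {
      x <- Biostrings::DNAStringSet(target_genomes[i])
      names(x) <- names(target_genomes)[i]
      x
    })
    names(tg) <- names(target_genomes)
    target_genomes <- tg
  }
  calls <- list()
  for (sp in names(target_genomes)) {
    mq <- map_queries(fq$queries, target_genomes[[sp]], k = k,
                      min_identity = min_identity, min_seg_len = min_seg_len,
                      unique_margin = unique_margin)
    data.table::setkey(mq, query_id)
    for (i in seq_len(nrow(fq$info))) {
      lid <- fq$info$locus_id[i]
      res <- call_presence(mq[paste0(lid, "|q5")], mq[paste0(lid, "|q3")],
                           fq$info$element_length[i], span_tol = span_tol,
                           adjacent_max = adjacent_max,
                           junction_min = junction_min,
                           require_junction = require_junction)
      calls[[length(calls) + 1L]] <- data.table::data.table(
        locus_id = lid, species = sp, state = res$state,
        flank5_mapped = res$evidence[["flank5_mapped"]],
        flank3_mapped = res$evidence[["flank3_mapped"]],
        colinear = res$evidence[["colinear"]],
        junction_support = res$evidence[["junction_support"]])
    }
  }
  data.table::rbindlist(calls)
}

#' Locus x species conservation matrix
#'
#' @param calls data.table from [call_alu_presence()] (needs `locus_id`,
#'   `species`, `state`).
#' @return list: `matrix` (loci x species; 1 present, 0 absent, NA
#'   inconclusive) and `species_summary` (data.table with the per-species
#'   present fraction over conclusive calls).
#' @export
conservation_matrix <- function(calls) {
  if (anyDuplicated(calls[, c("locus_id", "species")])) {
    stop("duplicate (locus, species) call")
  }
  code <- ifelse(calls$state == "present", 1L,
          ifelse(calls$state == "absent", 0L, NA_integer_))
  loci <- unique(calls$locus_id)
  species <- unique(calls$species)
  mat <- matrix(NA_integer_, length(loci), length(species),
                dimnames = list(loci, species))
  mat[cbind(match(calls$locus_id, loci), match(calls$species, species))] <- code
  summ <- data.table::data.table(
    species = species,
    n_conclusive = colSums(!is.na(mat)),
    present_fraction = colMeans(mat, na.rm = TRUE))
  list(matrix = mat, species_summary = summ)
}
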
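# Peak-to-gene linkage and the expression-change comparison for genes near
# the most opening / most closing peaks.

#' Link peaks to genes by TSS proximity
#'
#' Without an interaction table, every peak is linked to every gene whose TSS
#' lies within `max_dist` bp of the peak (distance 0 when the TSS falls
#' inside the peak). With one, links are restricted to the listed
#' (peak, gene) pairs that also satisfy the distance rule. Distances are
#' signed strand-aware: negative = peak upstream of the TSS.
#'
#' @param peaks peak `GRanges` with a `name` column.
#' @param genes width-1 TSS `GRanges` with `gene_id` and strand.
#' @param interactions optional data.frame/data.table with columns
#'   `peak_id`, `gene_id`.
#' @param max_dist maximum TSS distance in bp (default 10 kb).
#' @return data.table `peak_id`, `gene_id`, `distance`.
#' @export
link_peaks_to_genes <- function(peaks, genes, interactions = NULL,
                                max_dist = 10000L) {
  ext <- GenomicRanges::resize(genes, width = 2L * max_dist + 1L, fix = "center")
  ov <- GenomicRanges::findOverlaps(peaks, ext, ignore.strand = TRUE)
  if (!length(ov)) {
    return(data.table::data.table(peak_id = character(),
                                  gene_id = character(),
                                  distance = integer()))
  }
  pi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  tss <- GenomicRanges::start(genes)[gi]
  ps <- GenomicRanges::start(peaks)[pi]
  pe <- GenomicRanges::end(peaks)[pi]
  inside <- tss >= ps & tss <= pe
  # unsigned gap, then sign: upstream of the TSS (strand-aware) is negative
  gap <- ifelse(inside, 0L, pmin(abs(tss - ps), abs(tss - pe)))
  peak_left <- pe < tss
  gminus <- as.character(GenomicRanges::strand(genes))[gi] == "-"
  upstream <- ifelse(gminus, !peak_left, peak_left)
  dist_signed <- ifelse(inside, 0L, ifelse(upstream, -gap, gap))
  links <- data.table::data.table(
    peak_id = S4Vectors::mcols(peaks)$name[pi],
    gene_id = S4Vectors::mcols(genes)$gene_id[gi],
    distance = as.integer(dist_signed))
  links <- links[abs(links$distance) <= max_dist]
  if (!is.null(interactions)) {
    key <- paste(links$peak_id, links$gene_id)
    ikey <- paste(interactions$peak_id, interactions$gene_id)
    links <- links[key %in% ikey]
  }
  links
}

#' Expression change of genes linked to the most dynamic peaks
#'
#' Takes the genes linked to the `n_top` lowest-rank (most opening) and the
#' `n_top` highest-rank (most closing) peaks. A gene linked to both groups
#' is assigned to the group of its best-ranked peak (the peak closest to its
#' own extreme of the ranking). Reports group means, the two-sided
#' two-sample t statistic (Welch by default, pooled-variance with
#' `classic = TRUE`), and the per-group log2fc values for plotting.
#'
#' @param ranked ranked peak stats (needs `id`, `rank`).
#' @param links link table from [link_peaks_to_genes()].
#' @param expression data.frame with `gene_id`, `log2fc`.
#' @param n_top number of peaks per extreme (default 100).
#' @param classic use the pooled-variance Student t test instead of Welch.
#' @return list `mean_opening`, `mean_closing`, `t`, `p`, `n_opening`,
#'   `n_closing`, `values` (data.table `gene_id`, `group`, `log2fc`).
#' @export
group_expression_change <- function(ranked, links, expression, n_top = 100L,
                                    classic = FALSE) {
  m <- nrow(ranked)
  open_peaks <- ranked$id[ranked$rank <= n_top]
  close_peaks <- ranked$id[ranked$rank > m - n_top]
  lo <- links[links$peak_id %in% open_peaks]
  lc <- links[links$peak_id %in% close_peaks]
  # first-rank precedence: a gene linked to both extremes goes with its
  # lowest-ranked (most opening) peak, i.e. the opening group
  open_genes <- unique(lo$gene_id)
  close_genes <- setdiff(unique(lc$gene_id), open_genes)
  genes <- c(open_genes, close_genes)
  grp <- c(rep("opening", length(open_genes)), rep("closing", length(close_genes)))
  expr <- setNames(expression$log2fc, expression$gene_id)
  vals <- data.table::data.table(gene_id = genes, group = grp,
                                 log2fc = expr[genes])
  vals <- vals[!is.na(vals$log2fc)]
  xo <- vals$log2fc[vals$group == "opening"]
  xc <- vals$log2fc[vals$group == "closing"]
  if (length(xo) < 3 || length(xc) < 3) {
    stop(sprintf("too few linked genes per group (opening %d, closing %d; >= 3 required)",
                 length(xo), length(xc)))
  }
  tt <- t.test(xo, xc, var.equal = classic)
  list(mean_opening = mean(xo), mean_closing = mean(xc),
       t = unname(tt$statistic), p = tt$p.value,
       n_opening = length(xo), n_closing = length(xc), values = vals)
}
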
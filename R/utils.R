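#' @importFrom stats dhyper median pnorm rbinom rnbinom rnorm runif sd
#'   p.adjust binom.test fisher.test t.test lm coef quantile rpois wilcox.test
#'   var residuals cophenetic rlnorm cor ks.test setNames
#' @importFrom utils head tail
#' @importFrom data.table data.table fread fwrite rbindlist setorder setkey
#'   set .N
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Two-sided Fisher's exact test for large 2x2 tables
#'
#' `fisher.test()`'s network algorithm is not usable when cell counts run into
#' the millions (as they do for bp-resolution genome overlap tables), so the
#' two-sided p-value is computed directly from the hypergeometric density:
#' the sum of `dhyper()` over all tables at least as extreme (density no
#' larger than the observed one, the same convention `fisher.test()` uses).
#'
#' @param a,b,c,d cell counts of the 2x2 table, rows = condition 1/2,
#'   columns = outcome 1/2.
#' @return list with `odds_ratio` (sample odds ratio) and `p` (two-sided).
#' @keywords internal
fisher_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + c      # column 1 total
  n <- b + d      # column 2 total
  k <- a + b      # row 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  d_obs <- dhyper(a, m, n, k)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  or <- (a * d) / (b * c)
  list(odds_ratio = or, p = min(1, p))
}

#' Area under the ROC curve from two score vectors
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative (ties count 1/2).
#'
#' @param pos scores of positive cases.
#' @param neg scores of negative cases.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(pos, neg) {
  pos <- pos[is.finite(pos)]
  neg <- neg[is.finite(neg)]
  stopifnot(length(pos) > 0, length(neg) > 0)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Deterministic child seed
#'
#' Derives a stream-specific seed from a master seed so that independent
#' simulation stages do not share random streams. Kept below 2^31.
#' @keywords internal
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 7919L) %% 2147483587L
}
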
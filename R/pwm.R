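# Position weight matrices: construction, MEME-minimal text I/O, log-odds
# scoring, and exact p-value calibration of score thresholds by dynamic
# programming over the discretized score distribution (the FIMO approach).

#' Construct a position weight matrix
#'
#' @param name motif label.
#' @param probs L x 4 matrix of per-position base probabilities, columns
#'   A,C,G,T; every row must sum to 1 within `1e-3`.
#' @param background length-4 base probabilities of the background model
#'   (default uniform).
#' @param pseudocount small positive fraction mixed into `probs`
#'   (`p' = (p + pc * background) / (1 + pc)`), so all probabilities are in
#'   (0, 1] and log-odds scores stay finite.
#' @return an object of class `pwm` with elements `name`, `probs`,
#'   `background`, `pseudocount`, `length`.
#' @export
pwm <- function(name, probs, background = rep(0.25, 4), pseudocount = 0.001) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1) stop("PWM must have length >= 1")
  if (any(probs < 0)) stop("negative probability in PWM '", name, "'")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-3)) {
    stop(sprintf("PWM '%s': row %d sums to %.4f (must be 1 within 1e-3)",
                 name, which(abs(rs - 1) > 1e-3)[1], rs[abs(rs - 1) > 1e-3][1]))
  }
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-3,
            pseudocount > 0)
  probs <- sweep(probs, 1, rs, "/")
  probs <- (probs + pseudocount * matrix(background, nrow(probs), 4, byrow = TRUE)) /
    (1 + pseudocount)
  colnames(probs) <- DNA_BASES
  structure(
    list(name = name, probs = probs, background = background,
         pseudocount = pseudocount, length = nrow(probs)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  length %d  consensus %s\n", x$name, x$length,
              pwm_consensus(x)))
  invisible(x)
}

#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 1, which.max)], collapse = "")
}

#' Log-odds score matrix in bits
#'
#' @param pwm a [pwm()] object.
#' @return L x 4 matrix `log2(p / background)`.
#' @export
pwm_logodds <- function(pwm) {
  lo <- log2(sweep(pwm$probs, 2, pwm$background, "/"))
  colnames(lo) <- DNA_BASES
  lo
}

#' Reverse-complement a PWM
#' @export
pwm_reverse_complement <- function(pwm) {
  p <- pwm$probs[rev(seq_len(pwm$length)), rev(seq_len(4)), drop = FALSE]
  colnames(p) <- DNA_BASES
  out <- pwm
  out$probs <- p
  out$background <- pwm$background[4:1]
  out
}

#' Build a sharp PWM from a consensus sequence
#'
#' Convenience constructor for synthetic motifs: the consensus base gets
#' probability `p_consensus` at each position, the rest is split evenly.
#'
#' @export
pwm_from_consensus <- function(name, consensus, p_consensus = 0.85, ...) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% DNA_BASES))
  probs <- matrix((1 - p_consensus) / 3, length(bases), 4,
                  dimnames = list(NULL, DNA_BASES))
  probs[cbind(seq_along(bases), match(bases, DNA_BASES))] <- p_consensus
  pwm(name, probs, ...)
}

# ---- MEME-minimal text format ------------------------------------------------

#' Read motifs from MEME-minimal text
#'
#' Supports the minimal subset: optional `Background letter frequencies`
#' line, one or more `MOTIF <name>` blocks each followed by a
#' `letter-probability matrix:` header and its rows. Background defaults to
#' uniform; a pseudocount is applied on construction.
#'
#' @param path motif file.
#' @param pseudocount passed to [pwm()].
#' @return list of `pwm` objects, named by motif.
#' @export
read_pwm <- function(path, pseudocount = 0.001) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  background <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) && bg_i[1] < length(lines)) {
    toks <- strsplit(lines[bg_i[1] + 1], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    freq <- vals[!is.na(vals)]
    if (length(freq) == 4) background <- freq
  }
  motif_i <- grep("^MOTIF\\b", lines)
  if (!length(motif_i)) stop("no MOTIF blocks in ", path)
  out <- lapply(motif_i, function(i) {
    name <- strsplit(lines[i], "\\s+")[[1]][2]
    j <- i + 1
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j])) j <- j + 1
    if (j > length(lines)) stop("MOTIF '", name, "' has no letter-probability matrix")
    w <- suppressWarnings(as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[j])))
    rows <- list()
    k <- j + 1
    while (k <= length(lines) && grepl("^[-0-9.eE+ \t]+$", lines[k]) && nzchar(lines[k])) {
      rows[[length(rows) + 1]] <- as.numeric(strsplit(lines[k], "\\s+")[[1]])
      k <- k + 1
    }
    if (!is.na(w) && length(rows) != w) {
      stop(sprintf("MOTIF '%s': %d matrix rows but w=%d", name, length(rows), w))
    }
    pwm(name, do.call(rbind, rows), background = background,
        pseudocount = pseudocount)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write motifs as MEME-minimal text
#'
#' @param pwms a `pwm` or list of them.
#' @param path output path.
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  bg <- pwms[[1]]$background
  writeLines(c("Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", p$length), con)
    # remove the construction pseudocount so read_pwm(write_pwm(x)) round-trips
    raw <- p$probs * (1 + p$pseudocount) -
      p$pseudocount * matrix(p$background, p$length, 4, byrow = TRUE)
    raw <- pmax(raw, 0)
    raw <- sweep(raw, 1, rowSums(raw), "/")
    writeLines(apply(raw, 1, function(r) sprintf("%.6f %.6f %.6f %.6f",
                                                 r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- exact score-distribution calibration ------------------------------------

#' Calibrate a PWM score threshold at a target p-value
#'
#' Computes the exact distribution of the log-odds score of a random sequence
#' drawn from the PWM's background model, by position-wise convolution over
#' scores discretized to `granularity` bits. The threshold is the smallest
#' score `t` with `P(score >= t) <= alpha`; the discretization error of any
#' score is at most `L * granularity`.
#'
#' @param pwm a [pwm()] object.
#' @param alpha target p-value in (0, 1).
#' @param granularity score-bin width in bits (> 0).
#' @return a `pwm_calibration`: list with `pwm`, `alpha`, `granularity`,
#'   `threshold` (bits), `attained_alpha`, and the discrete survival function
#'   (`score_grid`, `survival`) used by [pwm_hit_pvalue()].
#' @export
pwm_score_threshold <- function(pwm, alpha, granularity = 1e-3) {
  stopifnot(alpha > 0, alpha < 1)
  if (granularity <= 0) stop("granularity must be > 0")
  lo <- pwm_logodds(pwm)
  k <- round(lo / granularity)          # integer scores per position/base
  # dist[i] = P(partial score == off + i - 1); grown position by position
  dist <- 1
  off <- 0L                              # current minimum integer score
  bg <- pwm$background
  for (l in seq_len(pwm$length)) {
    kl <- k[l, ]
    lo_l <- off + min(kl)
    width <- length(dist) + (max(kl) - min(kl))
    nd <- numeric(width)
    for (b in 1:4) {
      sh <- kl[b] - min(kl)
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * bg[b]
    }
    dist <- nd
    off <- lo_l
  }
  score_grid <- (off + seq_along(dist) - 1L) * granularity
  survival <- rev(cumsum(rev(dist)))
  # threshold over achievable scores only (bins with mass), so the reported
  # threshold is the smallest attainable score meeting the target
  ok <- which(survival <= alpha & dist > 0)
  if (length(ok)) {
    threshold <- score_grid[ok[1]]
    attained <- survival[ok[1]]
  } else {
    # degenerate case (e.g. a uniform PWM): no score is rare enough; report
    # the maximum attainable score and its exceedance probability
    threshold <- score_grid[length(score_grid)]
    attained <- survival[length(survival)]
  }
  structure(
    list(pwm = pwm, alpha = alpha, granularity = granularity,
         threshold = threshold, attained_alpha = attained,
         score_grid = score_grid, survival = survival),
    class = "pwm_calibration"
  )
}

#' P-value of a hit score under the calibrated background distribution
#'
#' @param calib a [pwm_score_threshold()] result.
#' @param score log-odds score(s) in bits.
#' @return `P(background score >= score)` per input score.
#' @export
pwm_hit_pvalue <- function(calib, score) {
  # snap to the nearest grid point; scores were produced on the same grid
  i <- findInterval(score - calib$granularity / 2, calib$score_grid) + 1L
  i <- pmin(pmax(i, 1L), length(calib$survival))
  out <- calib$survival[i]
  out[score > calib$score_grid[length(calib$score_grid)] + calib$granularity / 2] <- 0
  out
}
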
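#' @import methods
#' @importFrom GenomicRanges GRanges start end width strand seqnames mcols
#'   findOverlaps countOverlaps reduce shift resize
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits mcols<-
NULL

# ---- interval plumbing -------------------------------------------------------
#
# Intervals live in GRanges internally (1-based, closed, the Bioconductor
# convention); every reader converts from 0-based half-open BED coordinates on
# the way in and every writer converts back on the way out. The blast tabular
# boundary (AlignmentHit) keeps its native 1-based inclusive spans.

granges_from_bed0 <- function(chrom, start0, end0, strand = NULL, ...) {
  strand <- strand %||% rep(".", length(chrom))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

bed_strand <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  s
}

validate_bed_coords <- function(start0, end0, path) {
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0)
  if (length(bad)) {
    stop(sprintf("invalid interval in '%s' at line %d: start=%s end=%s (need 0 <= start < end)",
                 path, bad[1], start0[bad[1]], end0[bad[1]]))
  }
}

#' Read a BED or narrowPeak file
#'
#' @param path file path.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowPeak"`. Columns beyond
#'   the dialect's are ignored; missing columns are an error.
#' @return a `GRanges` (1-based internally; input is 0-based half-open).
#'   `bed6` adds `name` and `score` metadata columns; `narrowPeak` adds
#'   `name`, `score`, `signalValue`, `pValue`, `qValue`, `peak`.
#' @export
read_bed <- function(path, dialect = c("bed6", "bed3", "narrowPeak")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  ncol_need <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L)[[dialect]]
  if (file.size(path) == 0) {
    warning(sprintf("empty BED file: %s", path))
    return(GenomicRanges::GRanges())
  }
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1)),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(dt) == 0) {
    warning(sprintf("empty BED file: %s", path))
    return(GenomicRanges::GRanges())
  }
  if (ncol(dt) < ncol_need) {
    stop(sprintf("'%s': %d columns found, %d required for dialect %s",
                 path, ncol(dt), ncol_need, dialect))
  }
  start0 <- suppressWarnings(as.integer(dt[[2]]))
  end0 <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) stop(sprintf("malformed line %d in '%s': non-numeric coordinates", bad[1], path))
  validate_bed_coords(start0, end0, path)
  if (dialect == "bed3") {
    return(granges_from_bed0(dt[[1]], start0, end0))
  }
  gr <- granges_from_bed0(dt[[1]], start0, end0, strand = as.character(dt[[6]]),
                          name = as.character(dt[[4]]),
                          score = suppressWarnings(as.numeric(dt[[5]])))
  if (dialect == "narrowPeak") {
    S4Vectors::mcols(gr)$signalValue <- as.numeric(dt[[7]])
    S4Vectors::mcols(gr)$pValue <- as.numeric(dt[[8]])
    S4Vectors::mcols(gr)$qValue <- as.numeric(dt[[9]])
    S4Vectors::mcols(gr)$peak <- as.integer(dt[[10]])
  }
  gr
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr a `GRanges`; `name`/`score` metadata columns are used for bed6
#'   and narrowPeak dialects (defaults `"."` and 0).
#' @param path output path.
#' @param dialect `"bed3"`, `"bed6"` or `"narrowPeak"`.
#' @export
write_bed <- function(gr, path, dialect = c("bed6", "bed3", "narrowPeak")) {
  dialect <- match.arg(dialect)
  mc <- S4Vectors::mcols(gr)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (dialect != "bed3") {
    dt$name <- if ("name" %in% names(mc)) as.character(mc$name) else "."
    sc <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
    dt$score <- ifelse(is.finite(sc) & sc == round(sc), as.character(as.integer(round(sc))), as.character(sc))
    dt$strand <- bed_strand(gr)
  }
  if (dialect == "narrowPeak") {
    dt$signalValue <- if ("signalValue" %in% names(mc)) mc$signalValue else 0
    dt$pValue <- if ("pValue" %in% names(mc)) mc$pValue else -1
    dt$qValue <- if ("qValue" %in% names(mc)) mc$qValue else -1
    dt$peak <- if ("peak" %in% names(mc)) mc$peak else -1L
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ATAC fragment file
#'
#' Fragments are unstranded sequenced inserts, one per row:
#' `chrom  start  end  sample` with 0-based half-open coordinates.
#'
#' @param path TSV path (no header).
#' @return a `data.table` with columns `chrom`, `start`, `end`, `sample`
#'   (coordinates kept 0-based half-open, matching the file).
#' @export
read_fragments <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "sample"),
                          colClasses = list(character = c(1, 4)))
  validate_bed_coords(dt$start, dt$end, path)
  dt
}

#' @rdname read_fragments
#' @param fragments a fragment `data.table` as returned by [read_fragments()].
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(fragments[, c("chrom", "start", "end", "sample")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

fragments_to_granges <- function(fragments) {
  granges_from_bed0(fragments$chrom, fragments$start, fragments$end,
                    sample = fragments$sample)
}

# ---- RepeatMasker ------------------------------------------------------------

parse_paren <- function(x) as.integer(gsub("[()]", "", x))

#' Read a RepeatMasker .out annotation
#'
#' Standard layout: 3 header lines then whitespace-separated columns. Genomic
#' begin/end (1-based inclusive) are converted to the package's internal
#' convention; orientation `"C"` becomes minus strand; the repeat family is
#' the last component of the class/family column (`SINE/Alu` -> `Alu`).
#' Consensus length is reconstructed from the repeat begin/end/(left) columns.
#'
#' @param path path to a `.out` file.
#' @return `GRanges` with metadata columns `family`, `subfamily`,
#'   `consensus_length`.
#' @export
read_repeatmasker_out <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) <= 3) {
    warning(sprintf("no repeat records in %s", path))
    return(GenomicRanges::GRanges())
  }
  lines <- lines[-(1:3)]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14)) {
    stop(sprintf("RepeatMasker line %d has %d fields (>= 14 required)",
                 which(nf < 14)[1] + 3L, min(nf)))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:15))
  chrom <- m[, 5]
  start0 <- as.integer(m[, 6]) - 1L
  end0 <- as.integer(m[, 7])
  validate_bed_coords(start0, end0, path)
  ori <- m[, 9]
  strand <- ifelse(ori == "C", "-", "+")
  cls <- m[, 11]
  family <- vapply(strsplit(cls, "/"), function(p) p[length(p)], character(1))
  plus <- ori != "C"
  rend <- as.integer(m[, 13])
  left <- integer(length(lines))
  left[plus] <- parse_paren(m[plus, 14])
  left[!plus] <- parse_paren(m[!plus, 12])
  consensus_length <- rend + left
  bad <- which(is.na(consensus_length) | consensus_length <= 0)
  if (length(bad)) stop(sprintf("bad consensus coordinates at RepeatMasker line %d", bad[1] + 3L))
  granges_from_bed0(chrom, start0, end0, strand = strand,
                    family = family, subfamily = m[, 10],
                    consensus_length = consensus_length)
}

#' Write repeats in RepeatMasker .out layout
#'
#' Inverse of [read_repeatmasker_out()] for repeats carrying `family`,
#' `subfamily` and `consensus_length` metadata. Consensus begin/end are
#' emitted as a full-length match (1..consensus_length scaled to instance
#' length when shorter); adequate for fixtures and round-trips of the fields
#' this pipeline consumes.
#'
#' @param repeats `GRanges` with `family`, `subfamily`, `consensus_length`.
#' @param path output path.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query              matching          repeat             position in repeat",
    "score   div. del. ins.  sequence  begin    end          (left)   repeat            class/family     begin  end    (left)     ID",
    ""
  )
  mc <- S4Vectors::mcols(repeats)
  n <- length(repeats)
  clen <- mc$consensus_length
  ilen <- GenomicRanges::width(repeats)
  rend <- pmin(clen, ilen)
  rbeg <- rep(1L, n)
  rleft <- clen - rend
  strand <- bed_strand(repeats)
  cls <- ifelse(mc$family %in% c("Alu"), paste0("SINE/", mc$family),
         ifelse(mc$family %in% c("L1", "CR1"), paste0("LINE/", mc$family),
         ifelse(mc$family %in% c("ERVL", "ERVK"), paste0("LTR/", mc$family),
         ifelse(mc$family %in% c("hAT-Charlie"), paste0("DNA/", mc$family),
                mc$family))))
  lines <- vapply(seq_len(n), function(i) {
    if (strand[i] != "-") {
      rep_cols <- sprintf("%d %d (%d)", rbeg[i], rend[i], rleft[i])
      ori <- "+"
    } else {
      rep_cols <- sprintf("(%d) %d %d", rleft[i], rend[i], rbeg[i])
      ori <- "C"
    }
    sprintf("%d %.1f %.1f %.1f %s %d %d (%d) %s %s %s %s %d",
            1000L, 5.0, 0.0, 0.0,
            as.character(GenomicRanges::seqnames(repeats))[i],
            GenomicRanges::start(repeats)[i] - 1L + 1L,  # 1-based begin
            GenomicRanges::end(repeats)[i],
            0L, ori, mc$subfamily[i], cls[i], rep_cols, i)
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# ---- FASTA -------------------------------------------------------------------

#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# ---- genes and expression ----------------------------------------------------

#' Read gene TSSs from a BED6 file
#'
#' Each record is reduced to its strand-aware transcription start (a width-1
#' interval): the leftmost base for `+` genes, the rightmost for `-`.
#'
#' @param path BED6 path; column 4 is the gene id.
#' @return width-1 `GRanges` with `gene_id` metadata.
#' @export
read_genes <- function(path) {
  gr <- read_bed(path, "bed6")
  if (length(gr) == 0) return(gr)
  tss <- GenomicRanges::resize(gr, width = 1L, fix = "start")
  S4Vectors::mcols(tss) <- NULL
  S4Vectors::mcols(tss)$gene_id <- S4Vectors::mcols(gr)$name
  tss
}

#' Read a differential-expression table
#'
#' @param path TSV with a header containing at least `gene_id` and `log2fc`.
#' @export
read_de_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  stopifnot(all(c("gene_id", "log2fc") %in% names(dt)))
  dt
}

# ---- blast-style tabular alignments ------------------------------------------

#' Read 12-column blast-style tabular alignment hits
#'
#' Standard `outfmt 6` columns. Subject spans stay 1-based inclusive; a
#' reversed subject span (`sstart > send`) encodes a minus-strand hit.
#'
#' @param path TSV path (no header).
#' @return data.table with the canonical column names.
#' @export
read_alignment_hits <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
    col.names = c("query_id", "subject", "identity_pct", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore"),
    colClasses = list(character = c(1, 2)))
  if (any(dt$identity_pct < 0 | dt$identity_pct > 100)) {
    stop(sprintf("identity_pct outside [0,100] in %s", path))
  }
  if (any(dt$qstart < 1 | dt$qend < dt$qstart)) {
    stop(sprintf("invalid query span in %s", path))
  }
  dt
}
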
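#' Strand-specific nascent-transcription window counts
#'
#' Bins strand-specific run-on (GRO-seq) alignments into a window of
#' `± flank` bp around an insertion site. Reads overlapping the rRNA mask
#' are removed first, exact duplicates (same chrom, start, strand, length)
#' are collapsed when `dedup`, and each remaining read is assigned to the
#' bin containing its 5' end (the polymerase position in run-on data:
#' `start` on "+", `end - 1` on "-"). RPM uses the post-filter depth (all
#' reads surviving masking/dedup, inside the window or not).
#'
#' @param alignments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand`; e.g. from [read_bed()].
#' @param site list or vector `(ref, pos)`: chromosome name and 0-based
#'   insertion position.
#' @param flank half-window size in bp (default 10000).
#' @param n_bins number of equal-width bins tiling `[pos - flank,
#'   pos + flank)` (default 40, i.e. 500-bp bins at the default flank).
#' @param dedup collapse exact-duplicate alignments (default TRUE).
#' @param rrna_mask optional data.frame (`chrom`, `start`, `end`) of rRNA
#'   intervals to exclude.
#' @return object of class `WindowCounts`: list with `site`, `flank`,
#'   `depth`, `bins` (data.frame `bin`, `start`, `end`, `strand`, `count`,
#'   `rpm`) and `totals` (upstream/downstream per strand).
#' @export
window_counts <- function(alignments, site, flank = 10000L, n_bins = 40L,
                          dedup = TRUE, rrna_mask = NULL) {
  if (flank <= 0) stop("flank must be > 0")
  stopifnot(n_bins >= 1)
  aln <- as.data.frame(alignments, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(aln)))
  chrom <- as.character(site[[1L]])
  pos <- as.numeric(site[[2L]])
  if (!is.null(rrna_mask) && nrow(rrna_mask) && nrow(aln)) {
    q <- GenomicRanges::GRanges(aln$chrom,
                                IRanges::IRanges(aln$start + 1L, aln$end))
    m <- GenomicRanges::GRanges(rrna_mask$chrom,
                                IRanges::IRanges(rrna_mask$start + 1L,
                                                 rrna_mask$end))
    aln <- aln[!IRanges::overlapsAny(q, m), , drop = FALSE]
  }
  if (dedup && nrow(aln)) {
    key <- paste(aln$chrom, aln$start, aln$strand, aln$end - aln$start,
                 sep = "\r")
    aln <- aln[!duplicated(key), , drop = FALSE]
  }
  depth <- nrow(aln)
  p5 <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
  lo <- pos - flank
  width <- 2 * flank / n_bins
  inside <- aln$chrom == chrom & p5 >= lo & p5 < pos + flank
  bin_of <- floor((p5[inside] - lo) / width) + 1L
  strands <- aln$strand[inside]
  counts <- matrix(0, nrow = n_bins, ncol = 2L,
                   dimnames = list(NULL, c("+", "-")))
  for (st in c("+", "-")) {
    t <- table(factor(bin_of[strands == st], levels = seq_len(n_bins)))
    counts[, st] <- as.numeric(t)
  }
  bin_start <- lo + (seq_len(n_bins) - 1L) * width
  bins <- data.frame(bin = rep(seq_len(n_bins), 2L),
                     start = rep(bin_start, 2L),
                     end = rep(bin_start + width, 2L),
                     strand = rep(c("+", "-"), each = n_bins),
                     count = c(counts[, "+"], counts[, "-"]),
                     stringsAsFactors = FALSE)
  bins$rpm <- if (depth > 0) rpm(bins$count, depth) else 0
  upstream <- bins$end <= pos
  totals <- c(
    upstream_plus = sum(bins$count[upstream & bins$strand == "+"]),
    upstream_minus = sum(bins$count[upstream & bins$strand == "-"]),
    downstream_plus = sum(bins$count[!upstream & bins$strand == "+"]),
    downstream_minus = sum(bins$count[!upstream & bins$strand == "-"]))
  structure(list(site = list(chrom = chrom, pos = pos), flank = flank,
                 depth = depth, bins = bins, totals = totals),
            class = "WindowCounts")
}

#' @export
print.WindowCounts <- function(x, ...) {
  cat("WindowCounts at ", x$site$chrom, ":", x$site$pos, " (+/- ", x$flank,
      " bp), depth = ", x$depth, "\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' Convergent-transcription index
#'
#' Symmetry of strand-specific transcription: C = min(sense, antisense) /
#' max(sense, antisense), in [0, 1]. C near 1 means the locus is transcribed
#' at similar levels on both strands (convergent transcription); C = 0 when
#' one strand is silent; `NaN` (flagged undefined) when both are 0.
#'
#' @param sense_total,antisense_total non-negative read totals.
#' @export
convergence_index <- function(sense_total, antisense_total) {
  stopifnot(sense_total >= 0, antisense_total >= 0)
  if (sense_total == 0 && antisense_total == 0) return(NaN)
  if (sense_total == 0 || antisense_total == 0) return(0)
  min(sense_total, antisense_total) / max(sense_total, antisense_total)
}

#' Call convergent transcription at a window
#'
#' @param wc a [window_counts()] result.
#' @param side `"upstream"`, `"downstream"` or `"window"` (both sides).
#' @param c_min index threshold (default 0.2).
#' @param min_reads minimal per-strand read count (default 10).
#' @return list with `C`, `sense`, `antisense`, `convergent` (logical).
#' @export
convergence_call <- function(wc, side = c("window", "upstream", "downstream"),
                             c_min = 0.2, min_reads = 10L) {
  side <- match.arg(side)
  t <- wc$totals
  s <- switch(side,
              upstream = t[["upstream_plus"]],
              downstream = t[["downstream_plus"]],
              window = t[["upstream_plus"]] + t[["downstream_plus"]])
  a <- switch(side,
              upstream = t[["upstream_minus"]],
              downstream = t[["downstream_minus"]],
              window = t[["upstream_minus"]] + t[["downstream_minus"]])
  C <- convergence_index(s, a)
  list(C = C, sense = s, antisense = a,
       convergent = !is.nan(C) && C >= c_min && min(s, a) >= min_reads)
}

#' Read BED alignments into the 0-based alignment table
#'
#' @param path BED file (>= 3 columns; strand taken from column 6 when
#'   present).
#' @return data.frame with `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = strand, stringsAsFactors = FALSE)
}
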
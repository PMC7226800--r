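#' Write coverage or read-interval tracks for a reference
#'
#' `format = "bedgraph"` serializes the per-base RPM coverage of one strand
#' as sorted, non-overlapping 0-based half-open intervals (zero-coverage
#' runs omitted). `format = "bed"` writes the mapped read intervals as BED6
#' with the strand column and the (possibly fractional) count as score.
#'
#' @param profile a [library_profile()].
#' @param ref reference name present in the profile.
#' @param out output file path.
#' @param format `"bedgraph"` or `"bed"`.
#' @param strand strand for bedGraph output (`"+"` or `"-"`; ignored for
#'   BED, which keeps a strand column).
#' @param sizes read-length window (default 19:29).
#' @export
write_tracks <- function(profile, ref, out, format = c("bedgraph", "bed"),
                         strand = "+", sizes = 19:29) {
  format <- match.arg(format)
  r <- profile_ref(profile, ref)
  n <- nchar(r$seq)
  if (format == "bedgraph") {
    cov <- coverage_profile(profile, ref, strand = strand, normalize = TRUE,
                            sizes = sizes)
    runs <- rle(cov)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths  # 0-based
    keep <- runs$values != 0
    gr <- GenomicRanges::GRanges(
      seqnames = rep(ref, sum(keep)),
      ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
      score = runs$values[keep],
      seqlengths = stats::setNames(n, ref))
    rtracklayer::export(gr, out, format = "bedGraph")
  } else {
    h <- filter_hits(profile, ref, NULL, "both", sizes)
    gr <- GenomicRanges::GRanges(
      seqnames = if (nrow(h)) ref else character(),
      ranges = IRanges::IRanges(start = h$start + 1L, width = h$length),
      strand = h$strand,
      score = h$count,
      seqlengths = stats::setNames(n, ref))
    names(gr) <- if (nrow(h)) sprintf("read_%05d", seq_len(nrow(h))) else NULL
    rtracklayer::export(gr, out, format = "BED")
  }
  invisible(out)
}

#' Write an AnnotatedReference as FASTA (+ BED feature table)
#'
#' @param ref an [annotated_reference()].
#' @param fasta output FASTA path.
#' @param bed optional BED6 path for the feature intervals.
#' @export
write_reference <- function(ref, fasta, bed = NULL) {
  ss <- Biostrings::DNAStringSet(stats::setNames(ref$seq, ref$name))
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(bed) && nrow(ref$features)) {
    gr <- GenomicRanges::GRanges(
      seqnames = ref$name,
      ranges = IRanges::IRanges(start = ref$features$start + 1L,
                                end = ref$features$end),
      strand = ref$features$strand,
      seqlengths = stats::setNames(nchar(ref$seq), ref$name))
    names(gr) <- ref$features$label
    rtracklayer::export(gr, bed, format = "BED")
  }
  invisible(fasta)
}

#' Read an AnnotatedReference from FASTA + BED feature table
#'
#' @param fasta FASTA with a single reference sequence.
#' @param bed optional BED file of feature intervals (names = labels).
#' @export
read_reference <- function(fasta, bed = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L) stop("expected exactly one sequence in ", fasta)
  features <- NULL
  if (!is.null(bed)) {
    gr <- rtracklayer::import(bed, format = "BED")
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "+"
    features <- data.frame(
      label = if (!is.null(gr$name)) gr$name else
        sprintf("feature_%d", seq_along(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = strand, stringsAsFactors = FALSE)
  }
  annotated_reference(sub("\\s.*$", "", names(ss)[1L]), as.character(ss[[1L]]),
                      features)
}
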
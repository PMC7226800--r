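#' Library mapping profile
#'
#' Per-reference, per-strand counts of mapped read 5' ends. `hits` has one
#' row per (ref, strand, start, length): `start` is the 0-based position of
#' the leftmost aligned base, `pos5` the 0-based 5'-end position of the read
#' as sequenced (`start` on "+", `start + length - 1` on "-"), and `count`
#' the (possibly fractionally split) read multiplicity. `depth` is the RPM
#' denominator, `unmapped` the multiplicity that hit no reference.
#'
#' @param hits data.frame with columns `ref`, `strand`, `start`, `length`,
#'   `count` (`mismatches` optional).
#' @param depth library depth.
#' @param unmapped unmapped multiplicity.
#' @param refs named list of [annotated_reference()] objects.
#' @return object of class `LibraryProfile`.
#' @export
library_profile <- function(hits, depth, unmapped = 0, refs = list()) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  required <- c("ref", "strand", "start", "length", "count")
  if (!all(required %in% names(hits))) {
    stop("hits must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(hits)) {
    key <- paste(hits$ref, hits$strand, hits$start, hits$length, sep = "\r")
    agg <- rowsum(hits$count, group = key)
    first <- !duplicated(key)
    hits <- data.frame(ref = hits$ref[first], strand = hits$strand[first],
                       start = hits$start[first], length = hits$length[first],
                       count = agg[match(key[first], rownames(agg)), 1L],
                       stringsAsFactors = FALSE)
    hits <- hits[order(hits$ref, hits$start, hits$strand, hits$length), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  } else {
    hits <- data.frame(ref = character(), strand = character(),
                       start = integer(), length = integer(),
                       count = numeric(), stringsAsFactors = FALSE)
  }
  hits$pos5 <- ifelse(hits$strand == "+", hits$start,
                      hits$start + hits$length - 1L)
  if (is.null(names(refs))) names(refs) <- vapply(refs, `[[`, "", "name")
  structure(list(hits = hits, depth = depth, unmapped = unmapped,
                 refs = refs),
            class = "LibraryProfile")
}

#' @export
print.LibraryProfile <- function(x, ...) {
  cat("LibraryProfile: depth = ", x$depth, ", mapped weight = ",
      round(sum(x$hits$count), 2), ", unmapped = ", round(x$unmapped, 2),
      ", refs: ", paste(names(x$refs), collapse = ", "), "\n", sep = "")
  invisible(x)
}

profile_ref <- function(profile, ref) {
  if (!ref %in% names(profile$refs)) {
    stop("unknown reference '", ref, "'; available: ",
         paste(names(profile$refs), collapse = ", "))
  }
  profile$refs[[ref]]
}

# hamming mismatch counts for candidate starts (1-based) of `pat` in `subj`
mismatches_at <- function(pat, subj, starts) {
  if (!length(starts)) return(integer())
  as.integer(Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                         with.indels = FALSE))
}

#' Map one read against a set of small references
#'
#' Returns every position and strand on every reference where the read
#' aligns ungapped with at most `max_mm` mismatches (Hamming distance). For
#' "-" hits the read is reverse-complemented before comparison and its 5'
#' end sits at `start + length - 1`. Rows are ordered by (ref, start,
#' strand).
#'
#' @param seq read sequence (character) or a single-row ReadSet record.
#' @param refs a single [annotated_reference()] or (named) list of them.
#' @param max_mm maximal mismatch count, 0..3 (default 0).
#' @return data.frame with columns `ref`, `start`, `length`, `strand`,
#'   `mismatches` (0-based `start`).
#' @export
map_read <- function(seq, refs, max_mm = 0L) {
  stopifnot(max_mm >= 0L, max_mm <= 3L)
  if (inherits(refs, "AnnotatedReference")) refs <- list(refs)
  if (is.null(names(refs))) names(refs) <- vapply(refs, `[[`, "", "name")
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (nm in names(refs)) {
    subj <- Biostrings::DNAString(refs[[nm]]$seq)
    if (L > length(subj)) next
    for (st in c("+", "-")) {
      pat <- if (st == "+") fwd else rev
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                    with.indels = FALSE, fixed = TRUE)
      starts <- BiocGenerics::start(m)
      if (!length(starts)) next
      out[[length(out) + 1L]] <- data.frame(
        ref = nm, start = starts - 1L, length = L, strand = st,
        mismatches = mismatches_at(pat, subj, starts),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(ref = character(), start = integer(),
                      length = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$ref, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# bulk 0-mismatch matching of many same-length patterns via a PDict;
# returns data.frame(seq_index, start0) of exact hits on the given strand
match_exact_bulk <- function(seqs, subj, strand) {
  pats <- if (strand == "+") seqs else revcomp(seqs)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
  m <- Biostrings::matchPDict(pd, subj)
  starts <- BiocGenerics::start(m)
  n_per <- S4Vectors::elementNROWS(m)
  data.frame(seq_index = rep(seq_along(seqs), n_per),
             start0 = unlist(starts, use.names = FALSE) - 1L)
}

#' Map a collapsed read library against references
#'
#' Each read contributes its full multiplicity to every reference it hits.
#' Within one reference a multi-position read's count is split equally
#' across its positions (`multimap = "split"`) or counted fully at each
#' (`multimap = "all"`). Reads hitting no reference are tallied as
#' `unmapped`. Mapping with `max_mm = 0` uses a dictionary index per read
#' length; `max_mm > 0` falls back to per-read scanning.
#'
#' @param reads a `ReadSet`.
#' @param refs a single [annotated_reference()] or (named) list of them.
#' @param max_mm maximal mismatch count, 0..3 (default 0, the piRNA mapping
#'   convention).
#' @param multimap `"split"` (default) or `"all"` for within-reference
#'   multi-position reads.
#' @return a [library_profile()].
#' @export
map_library <- function(reads, refs, max_mm = 0L,
                        multimap = c("split", "all")) {
  multimap <- match.arg(multimap)
  stopifnot(inherits(reads, "ReadSet"))
  if (inherits(refs, "AnnotatedReference")) refs <- list(refs)
  if (!length(refs)) stop("empty reference set")
  if (is.null(names(refs))) names(refs) <- vapply(refs, `[[`, "", "name")
  rec <- reads$records
  n <- nrow(rec)
  hit_any <- rep(FALSE, n)
  hits <- list()
  usable <- !grepl("N", rec$seq, fixed = TRUE)
  for (nm in names(refs)) {
    subj <- Biostrings::DNAString(refs[[nm]]$seq)
    ref_rows <- list()
    if (max_mm == 0L) {
      for (w in unique(nchar(rec$seq[usable]))) {
        idx <- which(usable & nchar(rec$seq) == w)
        if (!length(idx) || w > length(subj)) next
        for (st in c("+", "-")) {
          bm <- match_exact_bulk(rec$seq[idx], subj, st)
          if (!nrow(bm)) next
          ref_rows[[length(ref_rows) + 1L]] <- data.frame(
            read = idx[bm$seq_index], start = bm$start0, length = w,
            strand = st, stringsAsFactors = FALSE)
        }
      }
    } else {
      for (i in which(usable)) {
        h <- map_read(rec$seq[i], refs[nm], max_mm = max_mm)
        if (!nrow(h)) next
        ref_rows[[length(ref_rows) + 1L]] <- data.frame(
          read = i, start = h$start, length = h$length, strand = h$strand,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(ref_rows)) next
    rr <- do.call(rbind, ref_rows)
    hit_any[unique(rr$read)] <- TRUE
    npos <- table(rr$read)
    w <- rec$count[rr$read]
    if (multimap == "split") w <- w / as.numeric(npos[as.character(rr$read)])
    hits[[length(hits) + 1L]] <- data.frame(
      ref = nm, strand = rr$strand, start = rr$start, length = rr$length,
      count = w, stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(ref = character(), strand = character(), start = integer(),
               length = integer(), count = numeric(), stringsAsFactors = FALSE)
  unmapped <- sum(rec$count[!hit_any])
  library_profile(hits, depth = reads$depth, unmapped = unmapped, refs = refs)
}

#' Ingest external alignments (SAM/BAM) into a LibraryProfile
#'
#' Loads ungapped short-read alignments produced by an external aligner
#' (e.g. genome-wide mapping), converting 1-based SAM coordinates to the
#' package's 0-based convention. Records flagged unmapped are tallied in
#' `unmapped`. Each alignment record contributes count 1.
#'
#' @param path SAM (text) or BAM file.
#' @param refs optional named list of [annotated_reference()] objects to
#'   attach (needed for region statistics requiring sequence).
#' @param depth RPM denominator; default = number of records (mapped +
#'   unmapped).
#' @return a [library_profile()].
#' @export
read_sam <- function(path, refs = list(), depth = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "strand", "pos", "qwidth")))[[1L]]
  is_unmapped <- bitwAnd(res$flag, 4L) > 0L | is.na(res$pos)
  n_unmapped <- sum(is_unmapped)
  keep <- !is_unmapped
  hits <- data.frame(ref = as.character(res$rname[keep]),
                     strand = as.character(res$strand[keep]),
                     start = res$pos[keep] - 1L,
                     length = res$qwidth[keep],
                     count = 1, stringsAsFactors = FALSE)
  if (is.null(depth)) depth <- length(res$flag)
  library_profile(hits, depth = depth, unmapped = n_unmapped, refs = refs)
}

#' Serialize a LibraryProfile hit table as TSV
#'
#' @param profile a `LibraryProfile`.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
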
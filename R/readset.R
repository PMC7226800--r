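#' Collapsed small-RNA read set
#'
#' Reads are stored collapsed: one record per distinct sequence with its
#' multiplicity. `total_reads` is the number of reads before collapsing and
#' is the default library depth used for RPM normalization (overridable via
#' [set_depth()]).
#'
#' @param seqs character vector of read sequences (expanded or collapsed).
#' @param counts integer multiplicities, recycled; default 1 per sequence.
#' @param provenance free-text label for bookkeeping.
#' @return An object of class `ReadSet`: list with `records` (data.frame
#'   `seq`, `count`), `total_reads`, `depth`, `provenance`.
#' @export
read_set <- function(seqs, counts = NULL, provenance = "") {
  seqs <- toupper(as.character(seqs))
  if (any(!nzchar(seqs))) stop("empty read sequence")
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  stopifnot(length(counts) == length(seqs), all(counts >= 1))
  if (length(seqs)) {
    agg <- rowsum(as.numeric(counts), group = seqs)
    records <- data.frame(seq = rownames(agg), count = as.numeric(agg[, 1L]),
                          stringsAsFactors = FALSE)
    records <- records[order(records$seq), , drop = FALSE]
    rownames(records) <- NULL
  } else {
    records <- data.frame(seq = character(), count = numeric(),
                          stringsAsFactors = FALSE)
  }
  total <- sum(records$count)
  structure(list(records = records, total_reads = total, depth = total,
                 provenance = provenance),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat("ReadSet: ", nrow(x$records), " distinct sequence(s), ",
      x$total_reads, " read(s), depth = ", x$depth,
      if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Override the normalization depth of a ReadSet
#'
#' The library depth used as the RPM denominator defaults to the number of
#' reads surviving preprocessing; it can be overridden (e.g. with the number
#' of genome-mapped reads) since "library depth" is a per-study convention.
#'
#' @param reads a `ReadSet`.
#' @param depth positive number.
#' @export
set_depth <- function(reads, depth) {
  stopifnot(inherits(reads, "ReadSet"), is.numeric(depth), depth > 0)
  reads$depth <- depth
  reads
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Identical sequences are collapsed with summed counts; `total_reads`
#' equals the number of input records, so the result is independent of
#' record order. Gzip-compressed input is accepted.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`; default guessed from the extension.
#' @return a [read_set()].
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) stop("failed to parse '", path, "' as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  if (!length(ss)) return(read_set(character(), provenance = basename(path)))
  read_set(as.character(ss), provenance = basename(path))
}

#' Write a ReadSet as FASTA or FASTQ
#'
#' Multiplicities are expanded to one record per read; FASTQ qualities are
#' constant placeholders (the pipeline is quality-agnostic).
#'
#' @param reads a `ReadSet`.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(inherits(reads, "ReadSet"))
  seqs <- rep(reads$records$seq, times = reads$records$count)
  ids <- sprintf("read_%06d", seq_along(seqs))
  if (format == "fasta") {
    writeLines(paste0(">", ids, "\n", seqs), path)
  } else {
    quals <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  }
  invisible(path)
}

# remove the longest read suffix matching a prefix of the adapter
# (>= min_overlap, exact match); iterated to a fixed point so the
# operation is idempotent
trim_adapter_one <- function(seq, adapter, min_overlap) {
  repeat {
    L <- nchar(seq)
    kmax <- min(L, nchar(adapter))
    trimmed <- FALSE
    if (kmax >= min_overlap) {
      for (k in seq(kmax, min_overlap)) {
        if (substr(seq, L - k + 1L, L) == substr(adapter, 1L, k)) {
          seq <- substr(seq, 1L, L - k)
          trimmed <- TRUE
          break
        }
      }
    }
    if (!trimmed || !nzchar(seq)) return(seq)
  }
}

#' Trim 3' adapters and apply the piRNA-size length filter
#'
#' For each read the longest suffix exactly matching a prefix of the adapter
#' (at least `min_adapter_overlap` bases) is removed, iterating until no such
#' suffix remains; reads whose trimmed length falls outside
#' `[min_len, max_len]` and reads containing N are dropped. The default
#' window 19-29 nt retains the small-RNA size classes (siRNA + piRNA);
#' trimmed length 18 is dropped (minimal length filter >18 nt). The
#' surviving read count becomes both `total_reads` and the default RPM depth.
#'
#' @param reads a `ReadSet`.
#' @param adapter 3' adapter sequence; `NULL` or `""` disables trimming.
#' @param min_len,max_len retained length window (defaults 19 and 29).
#' @param min_adapter_overlap minimal suffix/prefix match length (default 3).
#' @return a `ReadSet` of surviving, trimmed reads with attribute
#'   `retained_fraction` (surviving / input reads).
#' @export
preprocess <- function(reads, adapter = NULL, min_len = 19L, max_len = 29L,
                       min_adapter_overlap = 3L) {
  stopifnot(inherits(reads, "ReadSet"), min_len <= max_len)
  rec <- reads$records
  n_in <- reads$total_reads
  if (nrow(rec) == 0L) {
    out <- read_set(character(), provenance = reads$provenance)
    attr(out, "retained_fraction") <- NA_real_
    return(out)
  }
  seqs <- rec$seq
  if (!is.null(adapter) && nzchar(adapter)) {
    adapter <- toupper(adapter)
    seqs <- vapply(seqs, trim_adapter_one, "", adapter = adapter,
                   min_overlap = as.integer(min_adapter_overlap),
                   USE.NAMES = FALSE)
  }
  len <- nchar(seqs)
  keep <- len >= min_len & len <= max_len & !grepl("N", seqs, fixed = TRUE)
  out <- read_set(seqs[keep], counts = rec$count[keep],
                  provenance = reads$provenance)
  attr(out, "retained_fraction") <- if (n_in > 0) out$total_reads / n_in else NA_real_
  out
}
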
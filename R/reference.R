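#' Annotated reference sequence
#'
#' A small reference sequence (a transgene mosaic, a canonical transposon,
#' ...) together with strand-aware feature intervals in 0-based half-open
#' coordinates. Features carry unique labels; the transgene layout used
#' throughout this package is P5 / hsp70-1 / I-fragment / hsp70-2 /
#' mini-white / P3.
#'
#' @param name reference name (single string).
#' @param seq upper-case DNA string over A/C/G/T/N.
#' @param features `data.frame` with columns `label`, `start`, `end`,
#'   `strand` (0-based half-open; strand one of `"+"`, `"-"`).
#' @return An object of class `AnnotatedReference`: a list with elements
#'   `name`, `seq` (character) and `features` (data.frame).
#' @export
annotated_reference <- function(name, seq, features = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("reference sequence must be non-empty")
  if (grepl("[^ACGTN]", seq)) stop("reference sequence contains non-ACGTN characters")
  if (is.null(features)) {
    features <- data.frame(label = character(), start = integer(),
                           end = integer(), strand = character(),
                           stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  required <- c("label", "start", "end", "strand")
  if (!all(required %in% names(features))) {
    stop("features must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(features$label)) stop("feature labels must be unique")
  n <- nchar(seq)
  bad <- features$start < 0L | features$end > n | features$start >= features$end
  if (any(bad)) {
    stop("feature(s) outside [0, ", n, ") or empty: ",
         paste(features$label[bad], collapse = ", "))
  }
  structure(list(name = name, seq = seq, features = features),
            class = "AnnotatedReference")
}

#' @export
print.AnnotatedReference <- function(x, ...) {
  cat("AnnotatedReference '", x$name, "': ", nchar(x$seq), " bp, ",
      nrow(x$features), " feature(s)\n", sep = "")
  if (nrow(x$features)) print(x$features, row.names = FALSE)
  invisible(x)
}

#' @export
length.AnnotatedReference <- function(x) nchar(x$seq)

#' Look up a feature interval on a reference
#'
#' @param ref an [annotated_reference()].
#' @param label feature label, or `NULL` for the whole reference.
#' @return list with `start`, `end` (0-based half-open) and `label`.
#' @keywords internal
ref_region <- function(ref, label = NULL) {
  if (is.null(label) || identical(label, "whole")) {
    return(list(label = "whole", start = 0L, end = nchar(ref$seq)))
  }
  i <- match(label, ref$features$label)
  if (is.na(i)) {
    stop("unknown region '", label, "'; available: ",
         paste(ref$features$label, collapse = ", "))
  }
  list(label = label, start = ref$features$start[i], end = ref$features$end[i])
}

# reverse-complement for plain character vectors (U represented as T)
revcomp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)
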
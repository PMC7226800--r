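#' Reads-per-million normalization
#'
#' @param count non-negative read count (may be fractional after
#'   multi-mapper splitting).
#' @param depth positive library depth.
#' @return `1e6 * count / depth`.
#' @export
rpm <- function(count, depth) {
  if (any(depth <= 0)) stop("depth must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  1e6 * count / depth
}

# rows of profile$hits on `ref`, restricted by strand / size / 5'-in-region
filter_hits <- function(profile, ref, region = NULL, strand = "both",
                        sizes = 19:29) {
  r <- profile_ref(profile, ref)
  reg <- ref_region(r, region)
  h <- profile$hits
  h <- h[h$ref == ref & h$length %in% sizes, , drop = FALSE]
  if (strand %in% c("+", "-")) h <- h[h$strand == strand, , drop = FALSE]
  h[h$pos5 >= reg$start & h$pos5 < reg$end, , drop = FALSE]
}

# 5' base of each hit as sequenced: reference base at pos5 on "+",
# its complement on "-"
hit_first_base <- function(hits, refseq) {
  if (!nrow(hits)) return(character())
  base <- substring(refseq, hits$pos5 + 1L, hits$pos5 + 1L)
  ifelse(hits$strand == "-", complement_base(base), base)
}

#' Per-region small-RNA statistics
#'
#' Counts are restricted to reads whose 5' end lies inside the region and
#' whose length falls in `sizes`. `u1_fraction` is the multiplicity-weighted
#' fraction of reads whose 5' base, as sequenced, is U (represented as T) —
#' the primary-piRNA 1U bias. `rpm` uses the profile's recorded depth.
#'
#' @param profile a [library_profile()].
#' @param ref reference name.
#' @param region feature label, or `NULL`/`"whole"` for the full reference.
#' @param strand `"+"`, `"-"` or `"both"` (default).
#' @param sizes length window (default 19:29).
#' @return object of class `RegionStats`: list with `region`, `strand`,
#'   `n_reads`, `rpm`, `size_hist` (named by length), `u1_fraction`,
#'   `depth`.
#' @export
region_stats <- function(profile, ref, region = NULL, strand = "both",
                         sizes = 19:29) {
  r <- profile_ref(profile, ref)
  h <- filter_hits(profile, ref, region, strand, sizes)
  n <- sum(h$count)
  size_hist <- vapply(sizes, function(s) sum(h$count[h$length == s]), 0)
  names(size_hist) <- sizes
  u1 <- if (n > 0) {
    fb <- hit_first_base(h, r$seq)
    sum(h$count[fb == "T"]) / n
  } else NA_real_
  structure(list(ref = ref,
                 region = if (is.null(region)) "whole" else region,
                 strand = strand, n_reads = n,
                 rpm = rpm(n, profile$depth),
                 size_hist = size_hist, u1_fraction = u1,
                 depth = profile$depth),
            class = "RegionStats")
}

#' @export
print.RegionStats <- function(x, ...) {
  cat("RegionStats ", x$ref, ":", x$region, " [", x$strand, "]  n = ",
      round(x$n_reads, 2), "  RPM = ", signif(x$rpm, 4), "  1U = ",
      if (is.na(x$u1_fraction)) "NA" else sprintf("%.1f%%", 100 * x$u1_fraction),
      "\n", sep = "")
  invisible(x)
}

#' Per-base coverage of mapped reads on one strand
#'
#' @param profile a [library_profile()].
#' @param ref reference name.
#' @param strand `"+"` or `"-"`.
#' @param normalize divide by depth/1e6 (RPM per base) when `TRUE`.
#' @param sizes length window (default 19:29).
#' @return numeric vector of length `nchar(ref)`; element i is the summed
#'   multiplicity of reads covering base i (1-based vector over 0-based
#'   positions i-1).
#' @export
coverage_profile <- function(profile, ref, strand = "+", normalize = TRUE,
                             sizes = 19:29) {
  r <- profile_ref(profile, ref)
  n <- nchar(r$seq)
  h <- filter_hits(profile, ref, NULL, strand, sizes)
  if (!nrow(h)) {
    cov <- numeric(n)
  } else {
    ir <- IRanges::IRanges(start = h$start + 1L, width = h$length)
    cov <- as.numeric(IRanges::coverage(ir, weight = h$count, width = n))
  }
  if (normalize) cov <- cov / (profile$depth / 1e6)
  cov
}

#' Ping-pong 5'-overlap spectrum
#'
#' For every sense (+) read with 5' end at p and antisense (-) read with 5'
#' end at q in the region, the overlap length is d = q - p + 1; pairs with
#' 1 <= d <= 20 contribute weight `count_+ * count_-` (or 1 per occupied
#' position pair with `pair_weight = "unique"`). `f[d]` are the relative
#' frequencies, and `z10` the z-score of `f[10]` against the sample mean and
#' sd of the 19 other bins — the ping-pong signature statistic. `z10` is NA
#' (flagged) when there are no pairs or the background sd is zero.
#'
#' @param profile a [library_profile()].
#' @param ref reference name.
#' @param region feature label or `NULL` for the whole reference.
#' @param sizes length window, default 24:29 (the piRNA size class).
#' @param pair_weight `"product"` (default) or `"unique"`.
#' @return object of class `OverlapSpectrum`: list with `f` (length 20),
#'   `n_pairs`, `z10`.
#' @export
overlap_spectrum <- function(profile, ref, region = NULL, sizes = 24:29,
                             pair_weight = c("product", "unique")) {
  pair_weight <- match.arg(pair_weight)
  hp <- filter_hits(profile, ref, region, "+", sizes)
  hm <- filter_hits(profile, ref, region, "-", sizes)
  wp <- tapply(hp$count, hp$pos5, sum)
  wm <- tapply(hm$count, hm$pos5, sum)
  if (pair_weight == "unique") {
    if (length(wp)) wp[] <- 1
    if (length(wm)) wm[] <- 1
  }
  f <- numeric(20L)
  if (length(wp) && length(wm)) {
    p <- as.integer(names(wp))
    qs <- as.integer(names(wm))
    for (d in 1:20) {
      j <- match(p + d - 1L, qs)
      ok <- !is.na(j)
      if (any(ok)) f[d] <- sum(wp[ok] * wm[j[ok]])
    }
  }
  n_pairs <- sum(f)
  z10 <- NA_real_
  if (n_pairs > 0) {
    f <- f / n_pairs
    bg <- f[-10L]
    if (stats::sd(bg) > 0) z10 <- (f[10L] - mean(bg)) / stats::sd(bg)
  }
  structure(list(f = stats::setNames(f, 1:20), n_pairs = n_pairs, z10 = z10),
            class = "OverlapSpectrum")
}

#' @export
print.OverlapSpectrum <- function(x, ...) {
  cat("OverlapSpectrum: pair weight = ", round(x$n_pairs, 2),
      ", f[10] = ", signif(x$f[10L], 4), ", z10 = ",
      if (is.na(x$z10)) "NA (undefined)" else signif(x$z10, 4), "\n", sep = "")
  invisible(x)
}

#' Test for a ping-pong signature
#'
#' @param spectrum an [overlap_spectrum()].
#' @param z_min z-score threshold (default 1.96).
#' @return `TRUE`, `FALSE`, or `NA` when z10 is undefined.
#' @export
has_pingpong <- function(spectrum, z_min = 1.96) {
  if (is.na(spectrum$z10)) return(NA)
  spectrum$z10 >= z_min
}
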
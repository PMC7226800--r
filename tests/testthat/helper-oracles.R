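# Independent brute-force oracles and tiny fixture builders. These
# deliberately avoid the package's own helpers (own complement table, own
# string scans) so that tests compare two independent computations.

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(seq) {
  paste(rev(oracle_comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# exhaustive Hamming scan of one read against one reference, both strands;
# returns data.frame(start, strand, mismatches) sorted by (start, strand),
# 0-based starts
oracle_hamming_scan <- function(seq, refseq, max_mm) {
  ref_chars <- strsplit(refseq, "")[[1]]
  L <- nchar(seq)
  np <- length(ref_chars) - L + 1L
  out <- list()
  if (np >= 1L) {
    for (st in c("+", "-")) {
      pat <- if (st == "+") seq else oracle_revcomp(seq)
      pc <- strsplit(pat, "")[[1]]
      mm <- integer(np)
      for (i in seq_len(L)) {
        mm <- mm + (ref_chars[i:(i + np - 1L)] != pc[i])
      }
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        out[[st]] <- data.frame(start = hit - 1L, strand = st,
                                mismatches = mm[hit],
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# brute-force per-base coverage accumulation over a hit table (one strand)
oracle_coverage <- function(hits, ref_len) {
  cov <- numeric(ref_len)
  for (i in seq_len(nrow(hits))) {
    idx <- (hits$start[i] + 1L):(hits$start[i] + hits$length[i])
    cov[idx] <- cov[idx] + hits$count[i]
  }
  cov
}

# exhaustive sense/antisense 5'-overlap enumeration over uncollapsed reads:
# truth rows (strand, pos5, length); returns the absolute weight per
# overlap d = 1..20 (one unit per read pair)
oracle_overlap_weights <- function(truth, sizes = 24:29) {
  t <- truth[truth$length %in% sizes, , drop = FALSE]
  p5 <- t$pos5[t$strand == "+"]
  q5 <- t$pos5[t$strand == "-"]
  w <- numeric(20L)
  for (p in p5) {
    d <- q5 - p + 1L
    ok <- d >= 1L & d <= 20L
    if (any(ok)) {
      tb <- tabulate(d[ok], nbins = 20L)
      w <- w + tb
    }
  }
  w
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny deterministic transgene-like reference for unit tests
tiny_reference <- function(seed = 101L) {
  make_reference(seed, layout = c(`P5` = 60L, `hsp70-1` = 50L,
                                  `I-fragment` = 300L, `hsp70-2` = 50L,
                                  `mini-white` = 240L, `P3` = 60L),
                 name = "tiny-TG")
}

# profile built directly from an explicit hit table on a reference
manual_profile <- function(ref, hits, depth) {
  library_profile(hits, depth = depth, unmapped = 0,
                  refs = stats::setNames(list(ref), ref$name))
}
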
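#' Default piRNA size distribution (19-29 nt, peaked at 24-26)
#'
#' @return named numeric probability vector over lengths 19..29.
#' @export
default_size_dist <- function() {
  stats::setNames(c(0.02, 0.02, 0.03, 0.04, 0.06, 0.18, 0.22, 0.18,
                    0.12, 0.08, 0.05), 19:29)
}

#' Simulation parameters for a synthetic small-RNA library
#'
#' The defaults emulate an ovarian library from a strong, maternally
#' established transgenic piRNA cluster: emission over the whole transgene
#' dominated by the I-fragment, dual-strand reads, a moderate ping-pong
#' fraction, and the primary-piRNA 1U bias of 62% for non-pair reads.
#'
#' @param seed integer seed; fully determines the library.
#' @param n_reads number of reads (default 10000).
#' @param region_weights named emission probabilities per feature (must sum
#'   to 1). Default: I-fragment 0.55, mini-white 0.30, hsp70-1/2 0.05 each,
#'   P5/P3 0.025 each.
#' @param antisense_fraction probability a non-pair read is antisense
#'   (default 0.5, dual-strand cluster).
#' @param p_pingpong fraction of reads emitted as sense/antisense pairs
#'   whose 5' ends overlap by exactly 10 nt (default 0.3).
#' @param u1_bias probability beta that a read's 5' base is U/T
#'   (default 0.62).
#' @param size_dist probability vector over lengths 19..29; default
#'   [default_size_dist()].
#' @param maternal_scale multiplier on `n_reads` emulating differences in
#'   maternal piRNA deposition (default 1).
#' @param strict when `TRUE` (default) the 1U bias is realized by choosing
#'   5' positions whose reference-derived base already matches, so every
#'   read is an exact reference substring (0-mismatch mappable); when
#'   `FALSE` the 5' base is substituted, stressing mismatch-tolerant
#'   mapping.
#' @return list of class `SimParams`.
#' @export
sim_params <- function(seed, n_reads = 10000L, region_weights = NULL,
                       antisense_fraction = 0.5, p_pingpong = 0.3,
                       u1_bias = 0.62, size_dist = NULL,
                       maternal_scale = 1, strict = TRUE) {
  if (is.null(region_weights)) {
    region_weights <- c(`P5` = 0.025, `hsp70-1` = 0.05, `I-fragment` = 0.55,
                        `hsp70-2` = 0.05, `mini-white` = 0.30, `P3` = 0.025)
  }
  if (abs(sum(region_weights) - 1) > 1e-8) stop("region_weights must sum to 1")
  if (is.null(size_dist)) size_dist <- default_size_dist()
  stopifnot(abs(sum(size_dist) - 1) < 1e-8,
            antisense_fraction >= 0, antisense_fraction <= 1,
            p_pingpong >= 0, p_pingpong <= 1,
            u1_bias >= 0, u1_bias <= 1, maternal_scale > 0)
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 region_weights = region_weights,
                 antisense_fraction = antisense_fraction,
                 p_pingpong = p_pingpong, u1_bias = u1_bias,
                 size_dist = size_dist, maternal_scale = maternal_scale,
                 strict = strict),
            class = "SimParams")
}

#' Preset parameters for a weak transgenic cluster library
#'
#' Weak clusters produce piRNAs almost exclusively from the I-element
#' fragment (no spreading into mini-white), through ping-pong with
#' endogenous I-specific piRNAs.
#'
#' @param seed integer seed.
#' @param n_reads library size.
#' @param p_pingpong ping-pong pair fraction (default 0.6).
#' @param ... overrides passed to [sim_params()].
#' @export
sim_params_weak <- function(seed, n_reads = 10000L, p_pingpong = 0.6, ...) {
  sim_params(seed, n_reads = n_reads,
             region_weights = c(`P5` = 0, `hsp70-1` = 0, `I-fragment` = 1,
                                `hsp70-2` = 0, `mini-white` = 0, `P3` = 0),
             p_pingpong = p_pingpong, ...)
}

#' Preset parameters for a strong transgenic cluster library
#'
#' Strong clusters produce piRNAs from all transgene parts, with ping-pong
#' amplification, as after maternal establishment.
#'
#' @inheritParams sim_params_weak
#' @export
sim_params_strong <- function(seed, n_reads = 10000L, p_pingpong = 0.6, ...) {
  sim_params(seed, n_reads = n_reads, p_pingpong = p_pingpong, ...)
}

#' Generate a random annotated transgene-like reference
#'
#' A random sequence carrying the six transgene features in order (P5,
#' hsp70-1, I-fragment, hsp70-2, mini-white, P3), abutting and tiling the
#' sequence. The default I-fragment length is 2318 bp, the size of an
#' I-element segment spanning nucleotides 167-2484 of its canonical
#' (GenBank M14954) sequence.
#'
#' @param seed integer seed (deterministic output).
#' @param layout named integer vector of feature lengths in transgene
#'   order.
#' @param name reference name.
#' @return an [annotated_reference()].
#' @export
make_reference <- function(seed,
                           layout = c(`P5` = 500L, `hsp70-1` = 400L,
                                      `I-fragment` = 2318L,
                                      `hsp70-2` = 400L,
                                      `mini-white` = 3500L, `P3` = 500L),
                           name = "I-TG") {
  stopifnot(all(layout > 0), !is.null(names(layout)))
  set.seed(seed)
  total <- sum(layout)
  seq <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
               collapse = "")
  ends <- cumsum(as.integer(layout))
  starts <- c(0L, ends[-length(ends)])
  features <- data.frame(label = names(layout), start = starts, end = ends,
                         strand = "+", stringsAsFactors = FALSE)
  annotated_reference(name, seq, features)
}

# sample one element like sample(x, 1, prob) but safe for length-1 x
sample1 <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L, prob = prob)]
}

#' Simulate a small-RNA library with known ground truth
#'
#' Non-pair reads: emission region drawn from `region_weights`, strand from
#' `antisense_fraction`, length from `size_dist`, 5' position uniform
#' within the region (subject to the read fitting on the reference), and
#' the 5' base U/T with probability `u1_bias` (strict mode: by position
#' choice; otherwise by substitution). Ping-pong reads are emitted as
#' sense/antisense pairs whose 5' ends overlap by exactly 10 nt, with the
#' 1U rule applied to the sense partner. Fully deterministic per seed.
#'
#' @param ref an [annotated_reference()] (e.g. [make_reference()]).
#' @param params a [sim_params()] object.
#' @return list of class `SmallRnaSim` with elements `reads` (a collapsed
#'   [read_set()]), `truth` (data.frame: `id`, `region`, `strand`, `start`,
#'   `length`, `pos5`, `pair_id`, `seq`), `params`, `ref`.
#' @export
simulate_small_rna_library <- function(ref, params) {
  stopifnot(inherits(ref, "AnnotatedReference"), inherits(params, "SimParams"))
  missing_regions <- setdiff(names(params$region_weights)[params$region_weights > 0],
                             ref$features$label)
  if (length(missing_regions)) {
    stop("region weight on missing feature(s): ",
         paste(missing_regions, collapse = ", "))
  }
  set.seed(params$seed)
  ref_len <- nchar(ref$seq)
  ref_chars <- strsplit(ref$seq, "")[[1L]]
  # as-sequenced 5' base is T at position p: ref[p]=="T" on "+", "A" on "-"
  is_t <- list(`+` = ref_chars == "T", `-` = ref_chars == "A")

  n <- round(params$n_reads * params$maternal_scale)
  n_pairs <- round(n * params$p_pingpong / 2)
  n_single <- n - 2L * n_pairs
  w <- params$region_weights[params$region_weights > 0]
  lens <- as.integer(names(params$size_dist))
  feat <- ref$features

  region_range <- function(region) {
    i <- match(region, feat$label)
    c(feat$start[i], feat$end[i])  # 0-based half-open
  }
  pick_pos <- function(cand, strand, want_t, strict) {
    if (!length(cand)) return(NA_integer_)
    if (strict) {
      match_t <- is_t[[strand]][cand + 1L] == want_t
      if (any(match_t)) cand <- cand[match_t]
    }
    sample1(cand)
  }
  comp_chars <- chartr("ACGTN", "TGCAN", ref_chars)
  read_seq <- function(strand, start, len) {
    idx <- (start + 1L):(start + len)
    if (strand == "-") {
      paste(comp_chars[rev(idx)], collapse = "")
    } else {
      paste(ref_chars[idx], collapse = "")
    }
  }

  rows <- vector("list", n_single + 2L * n_pairs)
  k <- 0L
  emit <- function(region, strand, start, len, pos5, pair_id, seq) {
    k <<- k + 1L
    rows[[k]] <<- list(region = region, strand = strand, start = start,
                       length = len, pos5 = pos5, pair_id = pair_id,
                       seq = seq)
  }

  for (i in seq_len(n_single)) {
    region <- sample1(names(w), prob = w)
    rr <- region_range(region)
    strand <- if (stats::runif(1) < params$antisense_fraction) "-" else "+"
    len <- sample1(lens, prob = params$size_dist)
    want_t <- stats::runif(1) < params$u1_bias
    cand <- if (strand == "+") {
      seq.int(rr[1L], min(rr[2L] - 1L, ref_len - len))
    } else {
      seq.int(max(rr[1L], len - 1L), rr[2L] - 1L)
    }
    cand <- cand[cand >= 0 & cand < ref_len]
    p5 <- pick_pos(cand, strand, want_t, params$strict)
    if (is.na(p5)) next
    start <- if (strand == "+") p5 else p5 - len + 1L
    s <- read_seq(strand, start, len)
    if (!params$strict && want_t && substr(s, 1L, 1L) != "T") {
      substr(s, 1L, 1L) <- "T"
    }
    emit(region, strand, start, len, p5, NA_integer_, s)
  }

  for (j in seq_len(n_pairs)) {
    region <- sample1(names(w), prob = w)
    rr <- region_range(region)
    l1 <- sample1(lens, prob = params$size_dist)  # sense partner
    l2 <- sample1(lens, prob = params$size_dist)  # antisense partner
    want_t <- stats::runif(1) < params$u1_bias
    # sense 5' p: sense read [p, p+l1) on ref; antisense 5' q = p + 9,
    # antisense read [p+10-l2, p+10) on ref
    lo <- max(rr[1L], l2 - 10L, 0L)
    hi <- min(rr[2L] - 1L, ref_len - l1, ref_len - 10L)
    if (hi < lo) next
    p <- pick_pos(seq.int(lo, hi), "+", want_t, params$strict)
    if (is.na(p)) next
    s1 <- read_seq("+", p, l1)
    if (!params$strict && want_t && substr(s1, 1L, 1L) != "T") {
      substr(s1, 1L, 1L) <- "T"
    }
    emit(region, "+", p, l1, p, j, s1)
    q <- p + 9L
    start2 <- q - l2 + 1L
    emit(region, "-", start2, l2, q, j, read_seq("-", start2, l2))
  }

  rows <- rows[seq_len(k)]
  truth <- data.frame(
    id = sprintf("sim_%06d", seq_len(k)),
    region = vapply(rows, `[[`, "", "region"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = vapply(rows, `[[`, 0L, "start"),
    length = vapply(rows, `[[`, 0L, "length"),
    pos5 = vapply(rows, `[[`, 0L, "pos5"),
    pair_id = vapply(rows, `[[`, 0L, "pair_id"),
    seq = vapply(rows, `[[`, "", "seq"),
    stringsAsFactors = FALSE)
  reads <- read_set(truth$seq, provenance = sprintf("sim(seed=%d)", params$seed))
  structure(list(reads = reads, truth = truth, params = params, ref = ref),
            class = "SmallRnaSim")
}

#' Planted library profile from simulation ground truth
#'
#' Builds the LibraryProfile implied by the generator's own read placements
#' (each read counted once at its true position), bypassing the mapper.
#' Used for statistic-level recovery tests; the closed-loop tests map the
#' emitted sequences instead.
#'
#' @param sim a [simulate_small_rna_library()] result.
#' @return a [library_profile()].
#' @export
planted_profile <- function(sim) {
  stopifnot(inherits(sim, "SmallRnaSim"))
  t <- sim$truth
  hits <- data.frame(ref = sim$ref$name, strand = t$strand, start = t$start,
                     length = t$length, count = 1, stringsAsFactors = FALSE)
  library_profile(hits, depth = nrow(t), unmapped = 0,
                  refs = stats::setNames(list(sim$ref), sim$ref$name))
}

#' Planted per-region RPM from ground truth
#'
#' @param sim a [simulate_small_rna_library()] result.
#' @return named vector: `1e6 * reads-with-5'-in-region / n_reads` per
#'   feature of the reference.
#' @export
planted_region_rpm <- function(sim) {
  t <- sim$truth
  n <- nrow(t)
  vapply(stats::setNames(sim$ref$features$label, sim$ref$features$label),
         function(reg) {
           i <- match(reg, sim$ref$features$label)
           in_reg <- t$pos5 >= sim$ref$features$start[i] &
             t$pos5 < sim$ref$features$end[i]
           1e6 * sum(in_reg) / n
         }, 0)
}

#' Simulate strand-specific GRO-seq alignments around a site
#'
#' Reads are allocated to (bin, strand) cells by a multinomial draw over
#' the given rates; each read's 5' end is uniform within its bin. Bins tile
#' `[pos - flank, pos + flank)`.
#'
#' @param chrom chromosome name.
#' @param pos 0-based site position.
#' @param rates matrix `n_bins x 2` (columns `+`, `-`) of non-negative
#'   relative rates, or a single number per strand recycled over bins.
#' @param n_reads total reads.
#' @param seed integer seed.
#' @param flank half-window (default 10000).
#' @param read_length alignment length (default 50).
#' @return data.frame (`chrom`, `start`, `end`, `strand`) of 0-based
#'   half-open alignments, usable by [window_counts()].
#' @export
simulate_groseq <- function(chrom, pos, rates, n_reads, seed,
                            flank = 10000L, read_length = 50L) {
  set.seed(seed)
  if (is.vector(rates) && length(rates) == 2L) {
    rates <- matrix(rep(rates, each = 20L), ncol = 2L,
                    dimnames = list(NULL, c("+", "-")))
  }
  rates <- as.matrix(rates)
  if (is.null(colnames(rates))) colnames(rates) <- c("+", "-")
  if (any(rates < 0)) stop("rates must be >= 0")
  if (sum(rates) == 0) stop("all-zero rates")
  n_bins <- nrow(rates)
  width <- 2 * flank / n_bins
  cell <- sample.int(length(rates), n_reads, replace = TRUE,
                     prob = as.numeric(rates))
  bin <- (cell - 1L) %% n_bins + 1L
  strand <- colnames(rates)[(cell - 1L) %/% n_bins + 1L]
  lo <- pos - flank + (bin - 1L) * width
  p5 <- floor(lo + stats::runif(n_reads) * width)
  start <- ifelse(strand == "+", p5, p5 - read_length + 1L)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + read_length),
             strand = strand, stringsAsFactors = FALSE)
}

#' Simulate a ChIP-qPCR Ct table with a known true enrichment
#'
#' The control amplicon recovers a fixed baseline fraction of input; the
#' target's ChIP Ct is shifted by `-log2(epsilon)` relative to the control,
#' and Gaussian noise with sd `ct_noise_sd` is added to every ChIP Ct
#' measurement. With zero noise the pipeline recovers `epsilon` exactly.
#'
#' @param epsilon true relative enrichment (> 0).
#' @param ct_noise_sd Ct noise standard deviation (default 0.2).
#' @param n_bio,n_tech biological / technical replicates (default 3 each).
#' @param seed integer seed.
#' @param target,control,antibody labels for the table.
#' @param input_fraction fraction of chromatin used as input (default 0.1).
#' @param ct_input input Ct value (default 20).
#' @param control_recovery baseline percent-input recovery of the control
#'   amplicon (default 0.01).
#' @return long-format data.frame with columns `target`, `antibody`,
#'   `replicate`, `tech_rep`, `ct_chip`, `ct_input`, `input_fraction`.
#' @export
simulate_qpcr <- function(epsilon, ct_noise_sd = 0.2, n_bio = 3L,
                          n_tech = 3L, seed = 1L, target = "transgene-5P",
                          control = "rp49", antibody = "Rhi",
                          input_fraction = 0.1, ct_input = 20,
                          control_recovery = 0.01) {
  stopifnot(epsilon > 0, ct_noise_sd >= 0)
  set.seed(seed)
  ct_chip_control <- ct_input - log2(control_recovery / input_fraction)
  ct_chip_target <- ct_chip_control - log2(epsilon)
  grid <- expand.grid(tech_rep = seq_len(n_tech), replicate = seq_len(n_bio),
                      target = c(target, control), stringsAsFactors = FALSE)
  base_ct <- ifelse(grid$target == control, ct_chip_control, ct_chip_target)
  data.frame(target = grid$target, antibody = antibody,
             replicate = grid$replicate, tech_rep = grid$tech_rep,
             ct_chip = base_ct + stats::rnorm(nrow(grid), 0, ct_noise_sd),
             ct_input = ct_input, input_fraction = input_fraction,
             stringsAsFactors = FALSE)
}
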
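#' Percent-input recovery of a qPCR measurement
#'
#' Converts ChIP and input Ct values to the fraction of input chromatin
#' recovered, assuming perfect per-cycle doubling:
#' `r = f_in * 2^(ct_input - ct_chip)`, where `f_in` is the fraction of
#' chromatin used as input.
#'
#' @param ct_chip,ct_input cycle-threshold values (> 0).
#' @param input_fraction fraction of chromatin used as input (0 < f <= 1).
#' @return recovery fraction (vectorized).
#' @export
percent_input <- function(ct_chip, ct_input, input_fraction = 1) {
  stopifnot(all(ct_chip > 0), all(ct_input > 0),
            all(input_fraction > 0), all(input_fraction <= 1))
  input_fraction * 2^(ct_input - ct_chip)
}

#' Enrichment relative to a control locus
#'
#' ChIP recoveries are normalized to the input and then compared with the
#' recovery at a control genomic region (rp49 in the ovarian ChIP assays).
#'
#' @param target_r recovery at the target amplicon.
#' @param control_r recovery at the control amplicon (> 0).
#' @return E = target_r / control_r (vectorized).
#' @export
relative_enrichment <- function(target_r, control_r) {
  if (any(control_r == 0)) stop("control recovery must be > 0")
  target_r / control_r
}

p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Summarize relative enrichment over biological replicates
#'
#' Technical replicates are expected to be averaged (on the recovery scale)
#' before calling this. Reports the mean and SEM (= sd / sqrt(n)) over
#' biological replicates and a two-sided Welch t-test against the control
#' values, with the significance bands * p < 0.05, ** p < 0.01,
#' *** p < 0.001. With fewer than 2 replicates, or zero variance in both
#' groups, the p-value is flagged undefined (NA) — except that two constant
#' equal groups give p = 1.
#'
#' @param values per-biological-replicate relative enrichment E of the
#'   target.
#' @param control_values per-biological-replicate E of the comparison group.
#' @return object of class `EnrichmentResult`: list with `mean_e`, `sem`,
#'   `n_bio`, `p`, `stars`.
#' @export
summarize_replicates <- function(values, control_values) {
  stopifnot(all(values >= 0), all(control_values >= 0))
  n <- length(values)
  m <- mean(values)
  sem <- if (n > 1) stats::sd(values) / sqrt(n) else NA_real_
  p <- NA_real_
  if (n >= 2 && length(control_values) >= 2) {
    if (stats::sd(values) == 0 && stats::sd(control_values) == 0) {
      p <- if (m == mean(control_values)) 1 else NA_real_
    } else {
      p <- stats::t.test(values, control_values, var.equal = FALSE)$p.value
    }
  }
  structure(list(mean_e = m, sem = sem, n_bio = n, p = p,
                 stars = p_stars(p)),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("EnrichmentResult: E = ", signif(x$mean_e, 4), " +/- ",
      signif(x$sem, 3), " SEM (n = ", x$n_bio, "), p = ",
      if (is.na(x$p)) "NA" else signif(x$p, 3), " ", x$stars, "\n", sep = "")
  invisible(x)
}

#' ChIP-qPCR enrichment table from a long Ct table
#'
#' For each antibody and biological replicate, technical replicates are
#' averaged on the recovery scale; each target's recovery is then divided
#' by the control-amplicon recovery of the same replicate, and per-target
#' replicate enrichments are summarized with a Welch t-test against unity
#' (the control amplicon's self-enrichment).
#'
#' @param ct data.frame with columns `target`, `antibody`, `replicate`,
#'   `tech_rep`, `ct_chip`, `ct_input`, `input_fraction`; e.g. from
#'   [read_ct_table()] or [simulate_qpcr()].
#' @param control control amplicon label (default `"rp49"`).
#' @return data.frame with one row per (antibody, target): `mean_e`, `sem`,
#'   `n_bio`, `p`, `stars`.
#' @export
enrichment_table <- function(ct, control = "rp49") {
  ct <- as.data.frame(ct, stringsAsFactors = FALSE)
  need <- c("target", "antibody", "replicate", "tech_rep", "ct_chip",
            "ct_input", "input_fraction")
  stopifnot(all(need %in% names(ct)))
  if (!control %in% ct$target) {
    stop("control amplicon '", control, "' absent from the Ct table")
  }
  ct$recovery <- percent_input(ct$ct_chip, ct$ct_input, ct$input_fraction)
  # mean recovery per (antibody, target, bio replicate) over tech reps
  agg <- stats::aggregate(recovery ~ antibody + target + replicate,
                          data = ct, FUN = mean)
  out <- list()
  for (ab in unique(agg$antibody)) {
    a <- agg[agg$antibody == ab, , drop = FALSE]
    ctrl <- a[a$target == control, c("replicate", "recovery")]
    for (tg in setdiff(unique(a$target), control)) {
      t <- a[a$target == tg, c("replicate", "recovery")]
      j <- match(t$replicate, ctrl$replicate)
      if (anyNA(j)) stop("replicate(s) of '", tg, "' lack a ", control,
                         " control measurement")
      e <- relative_enrichment(t$recovery, ctrl$recovery[j])
      res <- summarize_replicates(e, rep(1, length(e)))
      out[[length(out) + 1L]] <- data.frame(
        antibody = ab, target = tg, mean_e = res$mean_e, sem = res$sem,
        n_bio = res$n_bio, p = res$p, stars = res$stars,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read a delimited Ct table
#'
#' @param path tab- or comma-delimited text with the columns used by
#'   [enrichment_table()].
#' @param sep field separator; default auto (tab if present in header).
#' @export
read_ct_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}
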
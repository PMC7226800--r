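#' Spreading index of piRNA production
#'
#' The ratio of mini-white RPM to I-fragment RPM from the same library,
#' both strands pooled. Spreading of piRNA production beyond the targeted
#' I-element fragment into the mini-white reporter is the hallmark of a
#' strong transgenic piRNA cluster; weak clusters produce piRNAs almost
#' exclusively from the I-fragment, giving S near 0.
#'
#' @param stats_i `RegionStats` for the I-element fragment.
#' @param stats_w `RegionStats` for the mini-white region.
#' @return S = rpm(mini-white) / rpm(I-fragment); 0 when mini-white RPM is
#'   0; `NaN` (flagged undefined) when the I-fragment RPM is 0 but
#'   mini-white is not.
#' @export
spreading_index <- function(stats_i, stats_w) {
  stopifnot(inherits(stats_i, "RegionStats"), inherits(stats_w, "RegionStats"))
  if (stats_i$depth != stats_w$depth) {
    stop("RegionStats come from profiles with different depths (",
         stats_i$depth, " vs ", stats_w$depth, ")")
  }
  if (stats_w$rpm == 0) return(0)
  if (stats_i$rpm == 0) return(NaN)
  stats_w$rpm / stats_i$rpm
}

#' Fold change between two RPM values
#'
#' @param rpm_a,rpm_b reads-per-million values.
#' @return `rpm_a / rpm_b`; `Inf` (flagged) when `rpm_b` is 0 and `rpm_a`
#'   is not; `NaN` when both are 0.
#' @export
fold_change <- function(rpm_a, rpm_b) {
  stopifnot(rpm_a >= 0, rpm_b >= 0)
  if (rpm_b == 0) return(if (rpm_a == 0) NaN else Inf)
  rpm_a / rpm_b
}

#' Classify a transgenic locus as a weak or strong piRNA cluster
#'
#' A locus is called strong when piRNA production has spread into the
#' mini-white reporter: spreading index `S >= s_min` and at least `n_min`
#' weighted mini-white reads. The call also records, for the I-fragment and
#' mini-white, whether the region shows a ping-pong signature (z10 >= z_min)
#' and whether mini-white piRNAs carry a primary signature (1U fraction >=
#' 0.5) — the configuration seen when a locus produces primary piRNAs from
#' mini-white without ping-pong amplification.
#'
#' @param stats named list of `RegionStats` containing at least
#'   `"I-fragment"` and `"mini-white"` (both strands pooled).
#' @param spectra named list of `OverlapSpectrum` for the same regions.
#' @param s_min spreading-index threshold (default 0.1).
#' @param n_min minimal mini-white weighted read count (default 50).
#' @param z_min ping-pong z-score threshold (default 1.96).
#' @return object of class `ClusterCall`: list with `label`
#'   (`"weak"`/`"strong"`), `spreading_index`, `z10` (named, per region),
#'   `mw_pingpong`, `mw_primary`, `thresholds`.
#' @export
classify_cluster <- function(stats, spectra, s_min = 0.1, n_min = 50,
                             z_min = 1.96) {
  need <- c("I-fragment", "mini-white")
  miss <- setdiff(need, names(stats))
  if (length(miss)) stop("missing RegionStats for: ", paste(miss, collapse = ", "))
  miss <- setdiff(need, names(spectra))
  if (length(miss)) stop("missing OverlapSpectrum for: ", paste(miss, collapse = ", "))
  s_i <- stats[["I-fragment"]]
  s_w <- stats[["mini-white"]]
  S <- spreading_index(s_i, s_w)
  strong <- !is.nan(S) && S >= s_min && s_w$n_reads >= n_min
  z10 <- c(`I-fragment` = spectra[["I-fragment"]]$z10,
           `mini-white` = spectra[["mini-white"]]$z10)
  mw_pp <- has_pingpong(spectra[["mini-white"]], z_min)
  mw_primary <- !is.na(s_w$u1_fraction) && s_w$u1_fraction >= 0.5
  structure(list(label = if (strong) "strong" else "weak",
                 spreading_index = S,
                 z10 = z10,
                 mw_pingpong = mw_pp,
                 mw_primary = mw_primary,
                 mw_n_reads = s_w$n_reads,
                 thresholds = c(s_min = s_min, n_min = n_min, z_min = z_min)),
            class = "ClusterCall")
}

#' @export
print.ClusterCall <- function(x, ...) {
  cat("ClusterCall: ", x$label, " (S = ",
      signif(x$spreading_index, 3), ", mini-white n = ",
      round(x$mw_n_reads, 1), ")\n  mini-white ping-pong: ",
      ifelse(is.na(x$mw_pingpong), "undefined", x$mw_pingpong),
      ", primary (1U >= 0.5): ", x$mw_primary, "\n", sep = "")
  invisible(x)
}

#' Per-region comparison table of two libraries
#'
#' Descriptive comparison of region RPM between two profiles (e.g. R vs I
#' background, maternal vs paternal inheritance): one row per region with
#' both RPM values and their fold change.
#'
#' @param profile_a,profile_b two [library_profile()] objects.
#' @param ref reference name present in both.
#' @param regions feature labels; default = all features of `ref`.
#' @param sizes length window (default 19:29).
#' @return data.frame with columns `region`, `rpm_a`, `rpm_b`,
#'   `fold_change` (a over b).
#' @export
compare_libraries <- function(profile_a, profile_b, ref, regions = NULL,
                              sizes = 19:29) {
  r <- profile_ref(profile_a, ref)
  if (is.null(regions)) regions <- r$features$label
  rows <- lapply(regions, function(reg) {
    a <- region_stats(profile_a, ref, reg, sizes = sizes)$rpm
    b <- region_stats(profile_b, ref, reg, sizes = sizes)$rpm
    data.frame(region = reg, rpm_a = a, rpm_b = b,
               fold_change = fold_change(a, b), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
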
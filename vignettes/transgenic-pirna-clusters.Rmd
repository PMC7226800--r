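---
title: "Quantifying transgenic piRNA clusters: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transgenic piRNA clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
```

## The biological setting

PIWI-interacting RNAs (piRNAs) are 24–29 nt germline small RNAs that
silence transposable elements in *Drosophila*. They are produced from
discrete genomic loci — piRNA clusters — and amplified post-transcriptionally
by the ping-pong cycle, in which reciprocal cleavage of sense and antisense
transcripts yields piRNA pairs whose 5′ ends overlap by exactly 10 nt.
Transgenes carrying a fragment of the I-element retrotransposon can be
converted into piRNA clusters when targeted by complementary piRNAs.
Two outcomes are observed: *weak* loci, where piRNA production stays
confined to the targeted I-element fragment, and *strong* loci, where
production spreads across the whole transgene, including the mini-white
reporter. This package implements the quantitative toolkit used to
characterize such loci from ovarian small-RNA sequencing, nascent-RNA
(GRO-seq) alignments and ChIP-qPCR tables, together with a seeded
synthetic-data generator so that every statistic has a ground-truth
recovery test.

## Small-RNA processing model

Reads are collapsed to (sequence, multiplicity) records. Adapter removal
deletes the longest read suffix that exactly matches a prefix of the 3′
adapter (at least 3 bases), and *iterates this to a fixed point*. A single
pass is the common convention, but it is not idempotent: a trimmed read
that happens to end in an adapter prefix would be trimmed again on a second
run. Iterating makes `preprocess()` idempotent — a property the test suite
checks — at the cost of occasionally removing a genuine genomic suffix that
mimics the adapter start (probability ≈ 4⁻³ per read for the minimal
overlap of 3). Reads outside 19–29 nt after trimming are discarded
(minimal length filter >18 nt), as are reads containing N, which cannot
be mapped under the 0-mismatch convention used throughout.

**Library depth.** RPM (reads per million) requires a denominator, and
"library depth" is a per-study convention; it is stored as an explicit,
overridable field (`set_depth()`). The default is the number of reads
surviving preprocessing, which is reproducible from the input alone.
Region RPM values scale linearly in this choice and all classification
statistics below are depth-ratio-free, so the choice affects reported
magnitudes, not calls.

## Mapping model

Reads are matched against small references (the ~7.6 kb transgene mosaic,
a canonical transposon) by ungapped Hamming-distance search on both
strands, with `max_mm` ∈ 0..3 mismatches (default 0, the piRNA mapping
convention; 1–3 are used for cross-element scans). On the minus strand the
read is reverse-complemented and its 5′ end sits at `start + length − 1`;
all coordinates are 0-based half-open internally and in BED/bedGraph
output, with SAM ingestion converting from 1-based. The implementation
uses a dictionary index over read-length groups for bulk exact matching
and a per-read scan for `max_mm > 0`; its contract is exact equivalence
with a brute-force Hamming scan, enforced by a property test over random
and mutation-planted reads at every mismatch level.

**Multi-mapping.** Within one reference, a read hitting several positions
has its count split equally across them (`multimap = "split"`, default;
`"all"` available). Across references a read contributes its full
multiplicity to each reference it hits, matching the per-reference RPM
semantics in which transgene-targeting and element-targeting piRNA levels
are reported separately.

## Region statistics and the 1U bias

A read belongs to a feature (I-fragment, mini-white, …) iff its **5′ end**
lies inside the feature. Full-containment rules make region counts
non-additive at boundaries; 5′-anchoring is the convention for 5′-defined
piRNA statistics and keeps counts additive across a partition of the
reference. The 1U fraction is the multiplicity-weighted fraction of reads
whose 5′ base *as sequenced* is U (T): the reference base at the 5′
position for sense reads and its complement for antisense reads. A 1U
fraction ≥ 0.5 is treated as a primary-piRNA signature; ping-pong
responder piRNAs lack it.

## Ping-pong 5′-overlap spectrum

For every sense read with 5′ end *p* and antisense read with 5′ end *q* on
the same reference and region, the overlap is `d = q − p + 1`. Pairs with
1 ≤ d ≤ 20 contribute the product of the two 5′-position multiplicities
(a `"unique"` mode counts occupied position pairs once, for
multiplicity-robust checks). The relative frequencies `f_d` sum to 1, and
the signature statistic is

> z₁₀ = (f₁₀ − mean(f_d, d≠10)) / sd(f_d, d≠10),

the z-score of the 10-nt overlap bin against the sample mean and standard
deviation of the 19 other bins. z₁₀ ≥ 1.96 is called a ping-pong
signature; z₁₀ is flagged undefined (NA) when there are no pairs or the
background sd is zero. The default size window is 24–29 nt (the piRNA
class); the spectrum is validated against exhaustive pair enumeration.

## Weak/strong classification

The spreading index is `S = RPM(mini-white) / RPM(I-fragment)`, both
strands pooled, from the same library (mismatched depths are an error).
A locus is called **strong** iff `S ≥ s_min` *and* the mini-white region
has at least `n_min` weighted reads; otherwise **weak**. The source
studies describe the dichotomy qualitatively (production confined to the
I-fragment vs spreading across the transgene), so the numeric thresholds
are explicitly configuration, recorded inside every `ClusterCall`. The
defaults `s_min = 0.1`, `n_min = 50` sit an order of magnitude between the
two described profiles: weak loci have mini-white RPM near zero while
strong loci produce mini-white piRNAs at a sizeable fraction of the
I-fragment level. The call also records whether mini-white shows ping-pong
(z₁₀ ≥ 1.96) or a primary signature (1U ≥ 0.5) — the configuration seen
when a paternally inherited locus produces primary mini-white piRNAs
without ping-pong. Classification is monotone in mini-white support and
invariant to depth rescaling; both are property-tested.

Comparisons between libraries (backgrounds, inheritance directions) are
reported descriptively as per-region RPM tables with fold changes
(`compare_libraries()`, `fold_change()`); no hypothesis test is attached,
since the underlying comparisons are made on single libraries per
condition.

## Nascent transcription and convergence

`window_counts()` bins strand-specific GRO-seq alignments in a ±10 kb
window around an insertion site (default 40 bins of 500 bp; bin width is
configuration since published "normalized counts" do not fix it). Reads
overlapping an rRNA mask are removed, exact duplicates — key (chrom,
start, strand, length) — are collapsed, and each surviving read is
assigned to the bin containing its **5′ end**, the polymerase position in
run-on data. RPM uses the post-filter depth. The convergent-transcription
index is `C = min(sense, antisense) / max(sense, antisense)` over a side
of the window; `C ≥ 0.2` with ≥ 10 reads per strand is called convergent.
Both thresholds are configuration: the published reasoning
("transcribed in both directions") is qualitative.

## ChIP-qPCR model

Recovery is `r = f_in · 2^(Ct_input − Ct_chip)` with amplification
efficiency fixed at 2.0 (efficiencies are not reported for the assays this
mirrors). Technical triplicates are averaged **on the recovery scale**
within each biological replicate — averaging on the Ct scale would
geometric-mean the recoveries and change the scale of the reported SEM —
then each target is normalized to the rp49 control recovery of the same
replicate. Replicate enrichments are summarized as mean ± SEM (sd/√n) with
a two-sided Welch t-test and the star bands \*, \*\*, \*\*\* at 0.05, 0.01
and 0.001. In the table driver the comparison group is the unit vector
(the control amplicon's self-enrichment is identically 1), making the test
a one-sample-style check of enrichment against unity. Note that at three
biological replicates a ±2·SEM band has only ~84% t-coverage; single-run
recovery checks should be read with that in mind (the test suite verifies
the coverage property itself over many seeds).

## The synthetic-data generator

`simulate_small_rna_library()` emulates ping-pong-amplified and primary
piRNA pools with known ground truth. Its defaults are fixed study
conditions, not tuning dials:

* `n_reads = 10⁴` — a desk-scale library large enough for binomial
  recovery of the printed 1U biases within ±2 standard errors.
* `region_weights` — strong-cluster preset: I-fragment 0.55, mini-white
  0.30, hsp70 promoters 0.05 each, P-element arms 0.025 each; weak preset:
  I-fragment 1.0. These mirror the described profiles (production either
  confined to the I-fragment or spread across the transgene with the
  I-fragment still dominant).
* `antisense_fraction = 0.5` — a dual-strand cluster.
* `p_pingpong` — fraction of reads emitted as 10-nt-overlap pairs; 0.6 in
  the cluster presets, 0 in primary-only pools.
* `u1_bias = 0.62` — the printed primary-piRNA 1U regime (0.70 for the
  insertion-flanking pool).
* `size_dist` — peaked at 24–26 nt over 19–29, the ovarian piRNA size
  profile.

In **strict mode** (default) the 1U bias is realized by *choosing* 5′
positions whose reference-derived base already matches the Bernoulli draw,
so every read is an exact reference substring and maps at 0 mismatches —
preserving the closed-loop identity that planted per-region RPMs equal
`region_stats()` output exactly after mapping. In substitution mode the 5′
base is overwritten instead, producing ≤1-mismatch reads that stress the
mismatch-tolerant mapper. The 1U rule applies to non-pair reads and to the
sense partner of each ping-pong pair; the antisense partner's 5′ position
is fixed by the 10-nt overlap, so its 5′ base cannot be chosen. The
printed 1U regimes this targets are ping-pong-free pools, so recovery
tests run at `p_pingpong = 0`. No sequencing-error model is included (the
mapping convention is 0 mismatches); mismatch injection for matcher tests
comes from the tests themselves.

What the generator does **not** emulate: genomic multi-mapping against a
full genome, non-uniform positional biases within a region (real coverage
is rugged), RNA secondary-structure or ligation biases, and the 10A bias
of responder piRNAs. Passing recovery tests therefore demonstrates
correctness of the statistics under the stated generative model, not
robustness to every property of real libraries.

`simulate_groseq()` allocates reads multinomially over (bin, strand) rates
with uniform 5′ positions within bins; `simulate_qpcr()` shifts the target
ChIP Ct by −log₂(ε) from a baseline control recovery of 1% of input and
adds Gaussian Ct noise (sd 0.2 by default), so ε is recovered exactly at
zero noise. All generators are fully determined by their integer seed
through R's Mersenne-Twister stream.

## Numerical choices and degenerate inputs

* Ratios are guarded: spreading index is 0 when mini-white RPM is 0 and
  NaN when the I-fragment RPM is 0; fold change of x over 0 is Inf (NaN
  for 0/0); the convergence index is NaN when both strands are 0.
* z₁₀ is NA when the pair set is empty or the background sd is 0.
* An empty FASTA/FASTQ yields an empty ReadSet, not an error; malformed
  records raise a parse error naming the file.
* bedGraph output omits zero-coverage runs and tiles the remaining
  coverage exactly: Σ(interval length × value) × depth/10⁶ equals the
  total mapped bases, a conservation law the suite asserts.
* Welch's t-test with two zero-variance groups returns p = 1 when the
  means agree and NA (flagged degenerate) otherwise.

## Problem sizes

The test suite and the analysis scripts use 10⁴-read libraries for
single-library statistics, 2 × 10³-read libraries across 100-seed
null/power and label-recovery sweeps, a 3 kb reference × 1000 reads × 4
mismatch levels for the matcher–oracle equivalence, and 10⁴-read GRO-seq
draws for convergence. These sizes were chosen so that each recovery test
sits comfortably inside its binomial or Poisson sampling envelope while a
full run of the suite stays in the minutes range on a laptop.

## Worked example

```{r example, eval = FALSE}
ref <- make_reference(1)
sim <- simulate_small_rna_library(ref, sim_params_strong(42, n_reads = 10000))
prof <- map_library(sim$reads, ref, max_mm = 0)

regions <- c(`I-fragment` = "I-fragment", `mini-white` = "mini-white")
stats <- lapply(regions, function(r) region_stats(prof, "I-TG", r))
spectra <- lapply(regions, function(r) overlap_spectrum(prof, "I-TG", r))
classify_cluster(stats, spectra)
```

## Known limitations

* Desk-scale references only: the matcher is quadratic-ish and meant for
  ≤ ~10 kb references; genome-wide alignments should be produced
  externally and ingested via `read_sam()`.
* Indels, quality scores and paired-end reads are out of scope.
* The weak/strong boundary is a configurable convention, not an estimated
  decision rule; borderline loci should be inspected via the underlying
  RPM table and spectra rather than trusted to the default thresholds.
* ChIP enrichment assumes perfect doubling; true efficiencies below 2
  compress Ct differences and bias E toward 1.
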
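# pirnakit

Quantification and classification of transgenic piRNA clusters from
small-RNA sequencing, GRO-seq and ChIP-qPCR data.

## The problem

In the *Drosophila* germline, PIWI-interacting RNAs (piRNAs, 24–29 nt)
silence transposons and are produced from piRNA clusters. A transgene
carrying a fragment of the I-element retrotransposon can itself be
converted into a piRNA cluster when targeted by complementary piRNAs.
Converted loci fall into two classes: **weak** clusters, which produce
piRNAs only from the targeted I-element fragment, and **strong** clusters,
where production spreads over the whole construct, including the
mini-white reporter. Deciding which is which — and whether the piRNAs are
ping-pong-amplified or primary — requires a small set of standard
statistics computed from mapped small-RNA reads. `pirnakit` implements
that toolkit for anyone analysing transgene- or element-derived small RNAs
against compact references, with a seeded synthetic-data generator so
every statistic has a ground-truth recovery test.

## What it computes

* **Preprocessing** — 3′-adapter trimming (exact suffix/prefix match,
  iterated to a fixed point), the >18 nt length filter with a 19–29 nt
  window, duplicate collapsing, explicit library-depth bookkeeping.
* **Mapping** — strand-aware ungapped matching of reads against small
  references at 0–3 mismatches (0 is the piRNA convention), with
  equal-split handling of within-reference multi-mappers, SAM/BAM
  ingestion for externally aligned data, and bedGraph/BED track output.
* **piRNA statistics** — per-region RPM = 10⁶·count/depth, size
  histograms, per-base coverage, the 5′-terminal uridine (1U) fraction,
  and the ping-pong 5′-overlap spectrum: relative frequencies f_d of
  sense/antisense 5′-overlaps d = 1..20 with the signature z-score

      z10 = (f10 − mean_{d≠10} f_d) / sd_{d≠10} f_d ,

  calling a ping-pong signature at z10 ≥ 1.96.
* **Cluster calls** — the spreading index
  S = RPM(mini-white)/RPM(I-fragment); a locus is *strong* iff S ≥ 0.1
  and mini-white has ≥ 50 weighted reads (thresholds configurable and
  recorded in the call), plus per-region fold-change comparisons across
  libraries.
* **Nascent transcription** — strand-specific GRO-seq window counts
  (±10 kb, rRNA masking, duplicate collapse, 5′-end bin assignment) and
  the convergent-transcription index
  C = min(sense, antisense)/max(sense, antisense).
* **ChIP-qPCR** — percent-input recovery r = f_in·2^(Ct_input − Ct_chip),
  enrichment relative to the rp49 control locus, replicate summaries with
  SEM, Welch t-test and the \*/\*\*/\*\*\* significance bands.
* **Synthetic data** — seeded generators for annotated transgene-like
  references (I-fragment length 2318 bp), piRNA libraries with tunable
  region weights, ping-pong fraction and 1U bias, GRO-seq alignments with
  per-bin strand rates, and qPCR Ct tables with planted enrichment.

## Worked example

Simulate a strong-cluster library, map it, and classify the locus:

```r
library(pirnakit)

ref <- make_reference(1)                     # P5/hsp70-1/I-fragment/hsp70-2/mini-white/P3
sim <- simulate_small_rna_library(ref, sim_params_strong(42, n_reads = 10000))
prof <- map_library(sim$reads, ref, max_mm = 0)

regions <- c(`I-fragment` = "I-fragment", `mini-white` = "mini-white")
stats   <- lapply(regions, function(r) region_stats(prof, "I-TG", r))
spectra <- lapply(regions, function(r) overlap_spectrum(prof, "I-TG", r))

stats[["I-fragment"]]
#> RegionStats I-TG:I-fragment [both]  n = 5607  RPM = 560700  1U = 50.7%
spectra[["I-fragment"]]
#> OverlapSpectrum: pair weight = 48098, f[10] = 0.09063, z10 = 24.17
classify_cluster(stats, spectra)
#> ClusterCall: strong (S = 0.517, mini-white n = 2899)
#>   mini-white ping-pong: TRUE, primary (1U >= 0.5): TRUE
```

Reading: 5607 of the 10,000 reads have their 5′ end in the I-fragment
(560,700 RPM at this library's depth), the 10-nt overlap bin towers over
the other overlap lengths (z10 = 24.2, a clear ping-pong signature), and
piRNA production has spread into mini-white (spreading index 0.52 with
2899 supporting reads), so the locus is called a strong cluster. A
worked ratio on published per-library levels of I-element-targeting
piRNAs — about 2000 RPM in an inducer background vs 28 RPM in a reactive
one — is `fold_change(2000, 28)` = 71.4, i.e. a ~70-fold difference.

## The analysis workflow

`analysis/` holds numbered drivers that run the whole study pipeline on
synthetic inputs and write tables under `results/`:

1. `01_simulate_libraries.R` — reference + four libraries (strong/weak ×
   maternal/paternal conditions).
2. `02_map_and_quantify.R` — preprocessing, 0-mismatch mapping,
   per-region RPM/1U table, bedGraph tracks.
3. `03_pingpong_and_classification.R` — overlap spectra, weak/strong
   calls, maternal-vs-paternal fold changes.
4. `04_groseq_convergence.R` — ±10 kb window counts and convergence
   calls at a transgene-bearing vs empty site.
5. `05_chip_enrichment.R` — ChIP-qPCR enrichment over rp49 with stars.

Run them in order from the repository root with `Rscript analysis/01_...`.

## Documentation

The methods vignette (`vignettes/transgenic-pirna-clusters.Rmd`) describes
the models, parameter defaults and their rationale, the synthetic
generator's assumptions, numerical edge-case handling, and known
limitations.
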
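#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs: a transgene-like annotated
# reference and small-RNA libraries emulating the four inheritance/background
# conditions (weak vs strong locus, ping-pong on the targeted fragment,
# primary-only production). Writes FASTA/FASTQ/TSV inputs for the later
# stages plus a JSON run log.

suppressPackageStartupMessages(library(pirnakit))
dir.create("results/input", recursive = TRUE, showWarnings = FALSE)

seed <- 20200901L
ref <- make_reference(seed)
write_reference(ref, "results/input/transgene.fa", "results/input/transgene.bed")
message("reference: ", ref$name, ", ", nchar(ref$seq), " bp, features ",
        paste(ref$features$label, collapse = "/"))

conditions <- list(
  strong_mat = sim_params_strong(seed + 1L, n_reads = 10000),
  weak_mat   = sim_params_weak(seed + 2L, n_reads = 10000),
  # paternal transmission of the strong locus: primary piRNAs from the
  # whole transgene, no ping-pong, 62% 1U
  strong_pat = sim_params(seed + 3L, n_reads = 10000, p_pingpong = 0,
                          u1_bias = 0.62),
  # paternal weak locus: low-level I-fragment-only production
  weak_pat   = sim_params_weak(seed + 4L, n_reads = 10000, p_pingpong = 0,
                               maternal_scale = 0.2)
)

log <- list(seed = seed, ref = ref$name, libraries = list())
for (nm in names(conditions)) {
  sim <- simulate_small_rna_library(ref, conditions[[nm]])
  write_reads(sim$reads, sprintf("results/input/%s.fastq", nm), "fastq")
  write.table(sim$truth, sprintf("results/input/%s.truth.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log$libraries[[nm]] <- list(n_reads = sim$reads$total_reads,
                              distinct = nrow(sim$reads$records),
                              planted_rpm = as.list(planted_region_rpm(sim)))
  message(nm, ": ", sim$reads$total_reads, " reads (",
          nrow(sim$reads$records), " distinct)")
}
jsonlite::write_json(log, "results/input/run_log.json", auto_unbox = TRUE,
                     pretty = TRUE)
message("inputs written under results/input/")
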
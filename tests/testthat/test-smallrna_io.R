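test_that("read_reads collapses duplicate sequences, order-independently", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGTACGTACGTACGTACGTACGT", ">b",
               "ACGTACGTACGTACGTACGTACGT"), fa)
  rs <- read_reads(fa, "fasta")
  expect_equal(nrow(rs$records), 1L)
  expect_equal(rs$records$count, 2)
  expect_equal(rs$total_reads, 2)

  # 1000 reads drawn from 4 distinct sequences -> 4 records summing to 1000
  set.seed(11)
  base4 <- replicate(4, random_dna(25))
  seqs <- sample(base4, 1000, replace = TRUE)
  writeLines(paste0(">r", seq_along(seqs), "\n", seqs), fa)
  rs <- read_reads(fa, "fasta")
  expect_equal(nrow(rs$records), 4L)
  expect_equal(sum(rs$records$count), 1000)
  expect_equal(rs$total_reads, 1000)
  # counts match direct enumeration of the input
  expect_equal(rs$records$count[match(names(table(seqs)), rs$records$seq)],
               as.numeric(table(seqs)))

  # order independence
  writeLines(paste0(">r", seq_along(seqs), "\n", rev(seqs)), fa)
  rs2 <- read_reads(fa, "fasta")
  expect_equal(rs$records, rs2$records)
})

test_that("FASTQ parsing and empty input behave as documented", {
  fq <- tempfile(fileext = ".fastq")
  seqs <- c(random_dna(25), random_dna(25), random_dna(25))
  writeLines(paste0("@r", 1:3, "\n", seqs, "\n+\n", strrep("I", 25)), fq)
  rs <- read_reads(fq)
  expect_equal(nrow(rs$records), 3L)
  expect_equal(rs$total_reads, 3)

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  rs0 <- read_reads(empty, "fasta")
  expect_equal(rs0$total_reads, 0)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "no-plus-line", "IIII"), bad)
  expect_error(read_reads(bad, "fastq"), "parse")
})

test_that("write_reads/read_reads round-trip preserves the read multiset", {
  set.seed(21)
  rs <- read_set(sample(replicate(6, random_dna(24)), 80, replace = TRUE))
  fa <- tempfile(fileext = ".fa")
  write_reads(rs, fa, "fasta")
  expect_equal(read_reads(fa, "fasta")$records, rs$records)
  fq <- tempfile(fileext = ".fq")
  write_reads(rs, fq, "fastq")
  expect_equal(read_reads(fq)$records, rs$records)
})

test_that("preprocess trims 3' adapters and applies the >18 nt filter", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert20 <- "ACGTTGCAACGTTGCAACGA"   # 20-mer not ending in adapter prefix
  rs <- read_set(paste0(insert20, adapter))
  out <- preprocess(rs, adapter)
  expect_equal(out$records$seq, insert20)

  # trimmed length 18 is dropped at min_len = 19
  insert18 <- substr(insert20, 1, 18)
  out18 <- preprocess(read_set(paste0(insert18, adapter)), adapter)
  expect_equal(out18$total_reads, 0)
  out19 <- preprocess(read_set(paste0(substr(insert20, 1, 19), adapter)),
                      adapter)
  expect_equal(out19$total_reads, 1)

  # read without adapter retained unchanged iff within 19..29
  clean25 <- "ACGTTGCAACGTTGCAACGATGCAC"
  expect_equal(preprocess(read_set(clean25), adapter)$records$seq, clean25)
  long35 <- paste0(clean25, "ACGTTGCAAC")
  expect_equal(preprocess(read_set(long35), adapter)$total_reads, 0)

  # partial adapter (>= min overlap) is trimmed; below-overlap suffix is not
  partial <- paste0(insert20, substr(adapter, 1, 4))
  expect_equal(preprocess(read_set(partial), adapter)$records$seq, insert20)

  # reads containing N are dropped
  expect_equal(preprocess(read_set(paste0("N", substr(clean25, 2, 25))),
                          adapter)$total_reads, 0)

  # depth and retained fraction bookkeeping
  rs2 <- read_set(c(paste0(insert20, adapter), clean25,
                    paste0(insert18, adapter)))
  out2 <- preprocess(rs2, adapter)
  expect_equal(out2$total_reads, 2)
  expect_equal(out2$depth, 2)
  expect_equal(attr(out2, "retained_fraction"), 2 / 3)
})

test_that("preprocess is idempotent on random adapter-bearing libraries", {
  set.seed(31)
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  for (rep in 1:5) {
    inserts <- replicate(60, random_dna(sample(15:32, 1)))
    with_ad <- paste0(inserts, substr(adapter, 1, sample(0:21, 60, TRUE)))
    rs <- read_set(with_ad)
    once <- preprocess(rs, adapter)
    twice <- preprocess(once, adapter)
    expect_equal(twice$records, once$records)
    expect_equal(twice$total_reads, once$total_reads)
  }
})

test_that("bedGraph tracks tile coverage and conserve mapped bases", {
  ref <- tiny_reference()
  depth <- 50
  # single plus-strand 25-mer at 0-based 100 -> one interval [100, 125)
  prof1 <- manual_profile(ref, data.frame(ref = "tiny-TG", strand = "+",
                                          start = 100L, length = 25L,
                                          count = 1), depth)
  bg <- tempfile(fileext = ".bedgraph")
  write_tracks(prof1, "tiny-TG", bg, "bedgraph", strand = "+")
  tab <- read.table(bg, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$V2, 100)
  expect_equal(tab$V3, 125)
  expect_equal(tab$V4, 1e6 / depth)

  # empty profile -> empty file
  prof0 <- manual_profile(ref, data.frame(ref = character(),
                                          strand = character(),
                                          start = integer(),
                                          length = integer(),
                                          count = numeric()), depth)
  bg0 <- tempfile(fileext = ".bedgraph")
  write_tracks(prof0, "tiny-TG", bg0, "bedgraph", strand = "+")
  expect_equal(length(readLines(bg0)), 0L)

  # overlapping reads: step function equals brute-force per-base sums,
  # and sum(length * value * depth / 1e6) over intervals = mapped bases
  set.seed(41)
  hits <- data.frame(ref = "tiny-TG",
                     strand = "+",
                     start = sample(0:600, 40, replace = TRUE),
                     length = sample(19:29, 40, replace = TRUE),
                     count = sample(1:5, 40, replace = TRUE))
  prof <- manual_profile(ref, hits, depth)
  bg2 <- tempfile(fileext = ".bedgraph")
  write_tracks(prof, "tiny-TG", bg2, "bedgraph", strand = "+")
  tab2 <- read.table(bg2, stringsAsFactors = FALSE)
  cov <- numeric(nchar(ref$seq))
  for (i in seq_len(nrow(tab2))) {
    cov[(tab2$V2[i] + 1):tab2$V3[i]] <- tab2$V4[i]
  }
  expect_equal(cov, oracle_coverage(hits, nchar(ref$seq)) / (depth / 1e6))
  expect_equal(sum((tab2$V3 - tab2$V2) * tab2$V4) * depth / 1e6,
               sum(hits$length * hits$count))
  # intervals sorted and non-overlapping
  expect_true(all(diff(tab2$V2) > 0))
  expect_true(all(tab2$V2[-1] >= tab2$V3[-nrow(tab2)]))

  # unknown reference names the available ones
  expect_error(write_tracks(prof, "nope", bg2), "tiny-TG")
})

test_that("BED output carries reads with strand and score", {
  ref <- tiny_reference()
  hits <- data.frame(ref = "tiny-TG", strand = c("+", "-"),
                     start = c(10L, 40L), length = c(25L, 25L),
                     count = c(2, 1))
  prof <- manual_profile(ref, hits, 100)
  bed <- tempfile(fileext = ".bed")
  write_tracks(prof, "tiny-TG", bed, "bed")
  tab <- read.table(bed, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 2L)
  expect_equal(sort(tab$V2), c(10, 40))
  expect_equal(tab$V3 - tab$V2, c(25, 25))
  expect_setequal(tab$V6, c("+", "-"))
})
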
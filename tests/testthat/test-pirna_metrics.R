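test_that("rpm normalization is exact, linear and guarded", {
  expect_equal(rpm(5, 1e6), 5)
  expect_equal(rpm(0, 123), 0)
  expect_equal(rpm(28, 1e6), 28)   # the low I-targeting piRNA level regime
  expect_error(rpm(5, 0), "depth")
  expect_error(rpm(-1, 10), "count")
  set.seed(101)
  for (i in 1:20) {
    cnt <- runif(1, 0, 1e4); dep <- runif(1, 1, 1e7); k <- runif(1, 0.1, 9)
    expect_equal(rpm(k * cnt, dep), k * rpm(cnt, dep))
    expect_equal(rpm(cnt, k * dep), rpm(cnt, dep) / k)
  }
})

test_that("region_stats restricts by 5' end, strand and size, and measures 1U", {
  ref <- tiny_reference()
  ifrag <- ref$features[ref$features$label == "I-fragment", ]

  # all planted reads start (as sequenced) with T -> u1 = 1
  tpos <- which(strsplit(ref$seq, "")[[1]] == "T") - 1L
  tpos <- tpos[tpos >= ifrag$start & tpos < ifrag$end - 30L][1:10]
  prof <- manual_profile(ref, data.frame(ref = "tiny-TG", strand = "+",
                                         start = tpos, length = 25L,
                                         count = 1), 10)
  st <- region_stats(prof, "tiny-TG", "I-fragment")
  expect_equal(st$u1_fraction, 1)
  expect_equal(st$n_reads, 10)
  expect_equal(st$rpm, 1e6)
  expect_equal(sum(st$size_hist), st$n_reads)

  # reads planted only inside I-fragment -> mini-white stats are zero
  mw <- region_stats(prof, "tiny-TG", "mini-white")
  expect_equal(mw$rpm, 0)
  expect_true(is.na(mw$u1_fraction))

  # membership is by 5' end: a "-" read whose 5' end is the last base of
  # the I-fragment belongs to it even though its body extends leftwards
  prof2 <- manual_profile(ref, data.frame(ref = "tiny-TG", strand = "-",
                                          start = ifrag$end - 25L,
                                          length = 25L, count = 1), 1)
  expect_equal(region_stats(prof2, "tiny-TG", "I-fragment")$n_reads, 1)
  # antisense 1U is read from the complement of the reference base
  base <- substr(ref$seq, ifrag$end, ifrag$end)
  expect_equal(region_stats(prof2, "tiny-TG", "I-fragment")$u1_fraction,
               as.numeric(base == "A"))

  # strand and size selectors
  expect_equal(region_stats(prof2, "tiny-TG", "I-fragment",
                            strand = "+")$n_reads, 0)
  expect_equal(region_stats(prof2, "tiny-TG", "I-fragment",
                            sizes = 24)$n_reads, 0)
  expect_error(region_stats(prof, "tiny-TG", "nope"), "unknown region")
})

test_that("simulated 1U bias is recovered within the binomial envelope", {
  ref <- make_reference(7)
  n <- 10000
  sim <- simulate_small_rna_library(
    ref, sim_params(111, n_reads = n, p_pingpong = 0, u1_bias = 0.62))
  u1 <- region_stats(planted_profile(sim), "I-TG")$u1_fraction
  se <- sqrt(0.62 * 0.38 / n)
  expect_lt(abs(u1 - 0.62), 2 * se)
})

test_that("coverage_profile equals brute-force per-base accumulation", {
  ref <- tiny_reference()
  n <- nchar(ref$seq)
  empty <- manual_profile(ref, data.frame(ref = character(),
                                          strand = character(),
                                          start = integer(),
                                          length = integer(),
                                          count = numeric()), 10)
  expect_equal(coverage_profile(empty, "tiny-TG", "+"), numeric(n))

  one <- manual_profile(ref, data.frame(ref = "tiny-TG", strand = "+",
                                        start = 100L, length = 25L,
                                        count = 1), 10)
  cov1 <- coverage_profile(one, "tiny-TG", "+", normalize = FALSE)
  expect_equal(which(cov1 > 0), 101:125)

  set.seed(121)
  hits <- data.frame(ref = "tiny-TG",
                     strand = sample(c("+", "-"), 60, replace = TRUE),
                     start = sample(0:(n - 30), 60, replace = TRUE),
                     length = sample(19:29, 60, replace = TRUE),
                     count = runif(60, 0.5, 4))
  prof <- manual_profile(ref, hits, 500)
  for (st in c("+", "-")) {
    want <- oracle_coverage(hits[hits$strand == st, ], n)
    expect_equal(coverage_profile(prof, "tiny-TG", st, normalize = FALSE),
                 want)
    expect_equal(coverage_profile(prof, "tiny-TG", st, normalize = TRUE),
                 want / (500 / 1e6))
  }
})

test_that("overlap_spectrum follows the 10-nt overlap convention", {
  ref <- tiny_reference()
  # one + read with 5' at 100; one - read covering [90,110) so 5' at 109:
  # overlap d = 10
  hits <- data.frame(ref = "tiny-TG", strand = c("+", "-"),
                     start = c(100L, 90L), length = c(25L, 20L),
                     count = c(1, 1))
  sp <- overlap_spectrum(manual_profile(ref, hits, 2), "tiny-TG",
                         sizes = 19:29)
  expect_equal(unname(sp$f[10]), 1)
  expect_equal(sum(sp$f), 1)
  expect_equal(sp$n_pairs, 1)

  # no antisense reads -> no pairs, z10 flagged undefined
  sp0 <- overlap_spectrum(manual_profile(ref, hits[1, ], 1), "tiny-TG",
                          sizes = 19:29)
  expect_equal(sp0$n_pairs, 0)
  expect_true(is.na(sp0$z10))
  expect_true(is.na(has_pingpong(sp0)))

  # multiplicity weighting is the product of 5'-position weights
  hits2 <- data.frame(ref = "tiny-TG", strand = c("+", "-", "-"),
                      start = c(100L, 90L, 95L), length = c(25L, 20L, 20L),
                      count = c(3, 2, 5))
  sp2 <- overlap_spectrum(manual_profile(ref, hits2, 10), "tiny-TG",
                          sizes = 19:29)
  # pairs: (100+,109-): d=10 weight 6; (100+,114-): d=15 weight 15
  expect_equal(unname(sp2$f[10]), 6 / 21)
  expect_equal(unname(sp2$f[15]), 15 / 21)
  expect_equal(sp2$n_pairs, 21)
  sp2u <- overlap_spectrum(manual_profile(ref, hits2, 10), "tiny-TG",
                           sizes = 19:29, pair_weight = "unique")
  expect_equal(unname(sp2u$f[10]), 0.5)
})

test_that("overlap_spectrum equals exhaustive pair enumeration on simulated libraries", {
  ref <- make_reference(7)
  for (seed in c(131, 132)) {
    sim <- simulate_small_rna_library(
      ref, sim_params(seed, n_reads = 5000, p_pingpong = 0.5))
    sp <- overlap_spectrum(planted_profile(sim), "I-TG", sizes = 24:29)
    w <- oracle_overlap_weights(sim$truth, sizes = 24:29)
    expect_equal(sp$n_pairs, sum(w))
    expect_equal(unname(sp$f), w / sum(w), tolerance = 1e-12)
    expect_equal(sum(sp$f), 1, tolerance = 1e-12)
    # planted 10-nt overlaps dominate
    expect_equal(unname(which.max(sp$f)), 10L)
  }
})
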
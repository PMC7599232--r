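test_that("zero-rate simulation returns the reference unchanged", {
  ref <- random_genome(2000, seed = 1)
  truth <- simulate_breed(ref, breed_sim_params(snp_rate = 0, n_hvr = 0, seed = 2))
  expect_identical(unclass(truth$breed), unclass(ref))
  expect_equal(nrow(truth$truth_calls), 0)
  expect_equal(nrow(truth$planted_hvrs), 0)
})

test_that("simulation is deterministic under a fixed seed", {
  ref <- random_genome(5000, seed = 1)
  p <- breed_sim_params(n_hvr = 3, seed = 7)
  t1 <- simulate_breed(ref, p)
  t2 <- simulate_breed(ref, p)
  expect_identical(unclass(t1$breed), unclass(t2$breed))
  expect_identical(t1$truth_calls, t2$truth_calls)
  expect_identical(t1$planted_hvrs, t2$planted_hvrs)
  rp <- read_sim_params(coverage = 2, seed = 9)
  expect_identical(simulate_reads(t1, rp), simulate_reads(t1, rp))
})

test_that("background site count is binomial and het fraction holds", {
  ref <- random_genome(100000, seed = 4)
  truth <- simulate_breed(ref, breed_sim_params(snp_rate = 0.01, n_hvr = 0,
                                                het_fraction = 0.3, seed = 5))
  n <- nrow(truth$truth_calls)
  expect_lt(abs(n - 1e5 * 0.01), 3 * sqrt(1e5 * 0.01 * 0.99))
  n_het <- sum(truth$truth_calls$genotype == "het")
  expect_lt(abs(n_het - n * 0.3), 3 * sqrt(n * 0.3 * 0.7))
  # every planted variant differs from the reference and is recorded once
  expect_false(any(truth$truth_calls$ref == truth$truth_calls$alt))
  expect_false(any(duplicated(truth$truth_calls[c("chrom", "pos")])))
})

test_that("planted variable regions are in bounds, non-overlapping, with a 3-run", {
  ref <- random_genome(30000, seed = 6)
  truth <- simulate_breed(ref, breed_sim_params(n_hvr = 12, seed = 7))
  ph <- truth$planted_hvrs
  expect_equal(nrow(ph), 12)
  expect_true(all(ph$start >= 0 & ph$end <= 30000))
  o <- order(ph$start)
  expect_true(all(ph$end[o][-12] <= ph$start[o][-1]))
  # each interval contains >= 3 consecutive substituted positions
  tc <- truth$truth_calls
  has_run <- vapply(seq_len(nrow(ph)), function(i) {
    pos <- sort(tc$pos[tc$chrom == ph$chrom[i] & tc$pos > ph$start[i] &
                         tc$pos <= ph$end[i]])
    any(diff(pos, lag = 2) == 2)
  }, logical(1))
  expect_true(all(has_run))
  # region substitutions are all homozygous
  in_hvr <- vapply(tc$pos, function(x) any(x > ph$start & x <= ph$end), logical(1))
  expect_true(all(tc$genotype[in_hvr] == "hom_alt"))
  # impossible placements error out
  expect_error(
    simulate_breed(random_genome(400, seed = 8),
                   breed_sim_params(n_hvr = 40, hvr_length_range = c(30, 36),
                                    seed = 9)),
    "reduce n_hvr")
})

test_that("read counts, exactness and per-site depth match expectations", {
  g <- random_genome(10000, seed = 10)
  reads <- simulate_reads(g, read_sim_params(read_length = 100, coverage = 1,
                                             seed = 11))
  expect_equal(nrow(reads), 100)

  # error-free reads from an undiverged genome are exact substrings
  # (forward or reverse-complement)
  seq1 <- unclass(g)[[1]]
  hit <- vapply(reads$seq, function(s) {
    grepl(s, seq1, fixed = TRUE) || grepl(revcomp(s), seq1, fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))

  # per-site depth is Poisson(coverage): mean over well-separated sites
  reads10 <- simulate_reads(g, read_sim_params(read_length = 100, coverage = 10,
                                               seed = 12))
  aln <- map_reads(reads10, g, mapper_params(max_mismatches = 0))
  sites <- seq(200, 9800, by = 200)  # > read length apart, so ~independent
  depth <- vapply(sites, function(p) {
    sum(aln$mapped & aln$pos < p & aln$pos + 100 >= p)
  }, numeric(1))
  expect_lt(abs(mean(depth) - 10), 3 * sqrt(10 / length(sites)))
})

test_that("reads with errors differ and het sites draw both haplotypes", {
  ref <- random_genome(5000, seed = 13)
  truth <- simulate_breed(ref, breed_sim_params(snp_rate = 0.02, n_hvr = 0,
                                                het_fraction = 1, seed = 14))
  reads <- simulate_reads(truth, read_sim_params(coverage = 25, seed = 15))
  aln <- map_reads(reads, ref, mapper_params())
  calls <- pileup_and_call(aln, ref, caller_params())
  het_truth <- truth$truth_calls[truth$truth_calls$genotype == "het", ]
  hit <- dplyr::semi_join(calls, het_truth, by = c("chrom", "pos"))
  expect_gt(nrow(hit), 0)
  # allele fractions concentrate around 1/2
  expect_lt(abs(mean(hit$alt_fraction) - 0.5), 0.1)

  withe <- simulate_reads(truth, read_sim_params(coverage = 2, error_rate = 0.05,
                                                 seed = 16))
  noerr <- simulate_reads(truth, read_sim_params(coverage = 2, error_rate = 0,
                                                 seed = 16))
  expect_false(identical(withe$seq, noerr$seq))
})

test_that("downsampling is exact, seeded and bounded", {
  g <- random_genome(10000, seed = 17)
  pool <- simulate_reads(g, read_sim_params(read_length = 100, coverage = 30,
                                            seed = 18))
  expect_identical(downsample_reads(pool, 30, 10000, 100), pool)
  sub5 <- downsample_reads(pool, 5, 10000, 100, seed = 19)
  expect_equal(nrow(sub5), round(5 * 10000 / 100))
  sub5b <- downsample_reads(pool, 5, 10000, 100, seed = 20)
  expect_equal(nrow(sub5b), nrow(sub5))
  expect_false(identical(sub5$id, sub5b$id))
  expect_error(downsample_reads(pool, 31, 10000, 100), "available")
})
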
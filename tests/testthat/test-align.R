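test_that("k-mer index retrieves every position and skips N k-mers", {
  g <- genome(c(chr1 = "ACGTACGT"))
  idx <- build_index(g, k = 4)
  hits <- kmer_hits(idx, "ACGT")
  expect_identical(hits$pos, c(0L, 4L))

  gN <- genome(c(chr1 = "ACGNACGT"))
  idxN <- build_index(gN, k = 4)
  expect_equal(nrow(kmer_hits(idxN, "ACGN")), 0)
  expect_equal(nrow(kmer_hits(idxN, "CGNA")), 0)
  expect_identical(kmer_hits(idxN, "ACGT")$pos, 4L)

  expect_error(build_index(g, k = 9), "shortest chromosome")
})

test_that("index lookups agree with a brute-force substring scan", {
  g <- random_genome(5000, seed = 21)
  idx <- build_index(g, k = 12)
  s <- unclass(g)[[1]]
  set.seed(22)
  for (i in 1:30) {
    start <- sample.int(5000 - 12, 1)
    km <- substr(s, start, start + 11)
    expect_identical(kmer_hits(idx, km)$pos,
                     as.integer(gregexpr(km, s, fixed = TRUE)[[1]]) - 1L)
  }
})

test_that("exact reads map with zero mismatches on both strands", {
  g <- random_genome(3000, seed = 23)
  s <- unclass(g)[[1]]
  idx <- build_index(g, k = 17)
  fwd <- map_read(substr(s, 101, 200), idx)
  expect_true(fwd$mapped)
  expect_equal(fwd$pos, 100L)
  expect_identical(fwd$strand, "+")
  expect_equal(fwd$n_mismatches, 0L)

  rev <- map_read(revcomp(substr(s, 101, 200)), idx)
  expect_true(rev$mapped)
  expect_equal(rev$pos, 100L)
  expect_identical(rev$strand, "-")
  expect_identical(rev$seq, substr(s, 101, 200))  # reference-forward oriented

  allN <- map_read(strrep("N", 100), idx)
  expect_false(allN$mapped)
})

test_that("mapper agrees with the exhaustive Hamming-scan oracle", {
  ref <- random_genome(2000, seed = 24)
  truth <- simulate_breed(ref, breed_sim_params(snp_rate = 0.01, n_hvr = 2,
                                                hvr_length_range = c(9, 20),
                                                seed = 25))
  reads <- simulate_reads(truth, read_sim_params(read_length = 100, coverage = 2,
                                                 error_rate = 0.005, seed = 26))
  params <- mapper_params()  # k=17, mm=3: floor(100/17) = 5 > 3 seed guarantee
  aln <- map_reads(reads, ref, params)
  for (i in seq_len(nrow(reads))) {
    oracle <- brute_force_map(ref, reads$seq[i], params$max_mismatches)
    expect_identical(aln$mapped[i], oracle$mapped, label = paste("read", i))
    if (oracle$mapped) {
      expect_equal(aln$n_mismatches[i], oracle$mm)
      expect_equal(aln$pos[i], oracle$pos)
      expect_identical(aln$strand[i], oracle$strand)
    }
  }
})

test_that("substituting a read's alleles never increases its mismatch count", {
  ref <- random_genome(2000, seed = 27)
  truth <- simulate_breed(ref, breed_sim_params(snp_rate = 0.02, n_hvr = 0,
                                                het_fraction = 0, seed = 28))
  reads <- simulate_reads(truth, read_sim_params(read_length = 100, coverage = 1,
                                                 seed = 29))
  before <- map_reads(reads, ref, mapper_params())
  after_g <- apply_substitutions(ref, truth$truth_calls)$genome
  after <- map_reads(reads, after_g, mapper_params())
  ok <- before$mapped
  expect_true(all(after$n_mismatches[ok] <= before$n_mismatches[ok]))
  expect_true(all(after$mapped[ok]))
})

test_that("error-free undiverged reads all map even at zero mismatch budget", {
  g <- random_genome(5000, seed = 30)
  reads <- simulate_reads(g, read_sim_params(coverage = 5, seed = 31))
  aln <- map_reads(reads, g, mapper_params(max_mismatches = 0))
  expect_equal(mapping_rate(aln), 1.0)
})

test_that("mapping rate and coverage ratio follow their definitions", {
  a <- tibble::tibble(read_id = letters[1:4], chrom = c("chr1", "chr1", NA, "chr1"),
                      pos = c(0L, 5L, NA, 20L), strand = c("+", "+", NA, "-"),
                      n_mismatches = c(0L, 1L, NA, 0L),
                      mapped = c(TRUE, TRUE, FALSE, TRUE),
                      seq = strrep("A", 10))
  expect_equal(mapping_rate(a), 0.75)
  expect_equal(mapping_rate(a[a$mapped, ]), 1.0)
  expect_error(mapping_rate(a[0, ]), "at least one")

  g <- genome(c(chr1 = strrep("A", 100)))
  one <- a[1, ]
  expect_equal(coverage_ratio(one, g), 0.10)
  expect_equal(coverage_ratio(a[0, ], g), 0)

  # recount oracle: per-base depth array from a SAM pass
  g2 <- random_genome(800, seed = 32)
  reads <- simulate_reads(g2, read_sim_params(read_length = 60, coverage = 2,
                                              seed = 33))
  aln <- map_reads(reads, g2, mapper_params())
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, g2, f)
  back <- read_sam(f)
  depth <- integer(800)
  for (i in which(back$mapped)) {
    span <- (back$pos[i] + 1):(back$pos[i] + nchar(back$seq[i]))
    depth[span] <- depth[span] + 1L
  }
  expect_equal(coverage_ratio(aln, g2), sum(depth > 0) / 800)
  expect_equal(mapping_rate(aln), mean(back$mapped))
})

test_that("ambiguous best placements honor require_unique_best", {
  g <- genome(c(chr1 = paste0(strrep("ACGTTGCAGGTCCATA", 2), "AAAA",
                              strrep("ACGTTGCAGGTCCATA", 2))))
  read <- strrep("ACGTTGCAGGTCCATA", 2)  # occurs twice
  strict <- map_read(read, build_index(g, 8), mapper_params(k = 8))
  expect_false(strict$mapped)
  loose <- map_read(read, build_index(g, 8),
                    mapper_params(k = 8, require_unique_best = FALSE))
  expect_true(loose$mapped)
  expect_equal(loose$pos, 0L)  # lowest (chrom, pos, strand) tie-break
})
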
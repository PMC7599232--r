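# Independent brute-force oracles and toy fixtures shared across tests.

# exhaustive all-position, both-strand Hamming scan with the same tie rules
# as the mapper: lowest (chrom, pos, strand) wins; ambiguous best unmapped
# when unique_best.
brute_force_map <- function(genome, read_seq, max_mm, unique_best = TRUE) {
  chroms <- names(unclass(genome))
  L <- nchar(read_seq)
  best <- max_mm + 1L
  hits <- list()
  for (ci in seq_along(chroms)) {
    g <- strsplit(unclass(genome)[[ci]], "")[[1]]
    n <- length(g)
    if (n < L) next
    win <- matrix(g[outer(0:(L - 1L), seq_len(n - L + 1L), "+")], nrow = L)
    for (strand in c("+", "-")) {
      r <- strsplit(if (strand == "+") read_seq else revcomp(read_seq), "")[[1]]
      mm <- colSums(win != r)
      for (p in which(mm <= max_mm)) {
        hits[[length(hits) + 1L]] <- list(chrom_i = ci, pos = p - 1L,
                                          strand = strand, mm = mm[p])
      }
    }
  }
  if (length(hits) == 0) return(list(mapped = FALSE))
  mms <- vapply(hits, `[[`, numeric(1), "mm")
  best <- min(mms)
  cand <- hits[mms == best]
  if (unique_best && length(cand) > 1) return(list(mapped = FALSE))
  ord <- order(vapply(cand, `[[`, numeric(1), "chrom_i"),
               vapply(cand, `[[`, numeric(1), "pos"),
               vapply(cand, `[[`, character(1), "strand"))
  b <- cand[[ord[1]]]
  list(mapped = TRUE, chrom = chroms[b$chrom_i], pos = b$pos,
       strand = b$strand, mm = as.integer(best))
}

# run-length scan over two base vectors; N breaks runs without mismatching
brute_force_hvr <- function(a_chars, b_chars, min_run = 3L) {
  mism <- a_chars != b_chars & a_chars != "N" & b_chars != "N"
  out <- list()
  run <- 0L
  for (i in seq_along(mism)) {
    if (mism[i]) run <- run + 1L else {
      if (run >= min_run) out[[length(out) + 1L]] <- c(i - 1L - run, i - 1L)
      run <- 0L
    }
  }
  if (run >= min_run) {
    out[[length(out) + 1L]] <- c(length(mism) - run, length(mism))
  }
  out
}

# exhaustive set comparison of two callsets keyed on locus+alleles+genotype
brute_force_compare <- function(test, gold) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, x$genotype)
  tk <- key(test)
  gk <- key(gold)
  tp <- sum(tk %in% gk)
  list(tp = tp, fp = length(tk) - tp, fn = length(gk) - tp)
}

# random small callset over a toy genome
random_callset <- function(n, n_pos = 40) {
  pos <- sort(sample.int(n_pos * 10, n))
  x <- callset(chrom = "chr1", pos = pos,
               ref = sample(c("A", "C", "G", "T"), n, TRUE),
               alt = sample(c("A", "C", "G", "T"), n, TRUE),
               genotype = sample(c("hom_alt", "het"), n, TRUE))
  x[x$ref != x$alt, , drop = FALSE]
}

# Toy construction of the consecutive-mismatch recovery scenario: a
# reference, a "breed" with three adjacent substitutions, and three reads
# whose spans stagger across the substituted run so each round of
# substitution makes one more read mappable at max_mismatches = 1.
fig2_fixture <- function(seed = 5) {
  ref <- random_genome(120, seed = seed)
  chars <- strsplit(unclass(ref)[[1]], "")[[1]]
  p <- 60L  # first substituted position (1-based)
  breed <- chars
  for (i in 0:2) {
    breed[p + i] <- setdiff(c("A", "C", "G", "T"), chars[p + i])[1]
  }
  breed_seq <- paste(breed, collapse = "")
  sub_read <- function(s, e) substr(breed_seq, s, e)
  reads <- tibble::tibble(
    id = c("read1", "readX", "readY"),
    seq = c(sub_read(p - 19L, p),        # covers the run's 1st base only
            sub_read(p - 12L, p + 1L),   # covers bases 1-2 of the run
            sub_read(p - 17L, p + 2L)),  # covers all 3 run bases
    qual = NA_character_
  )
  list(ref = ref, breed = genome(c(chr1 = breed_seq)), reads = reads, p = p)
}
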
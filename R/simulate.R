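# run expr with a temporarily-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# derive a per-round / per-step child seed below 2^31
child_seed <- function(seed, step) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1000003 + step * 7919) %% 2147483629
}

BASES <- c("A", "C", "G", "T")

#' Generate a random reference genome
#'
#' Uniform i.i.d. bases; the starting material for simulation-backed tests
#' and demos.
#'
#' @param length Total genome length in bases.
#' @param n_chroms Number of chromosomes (equal split, remainder on the last).
#' @param seed RNG seed (`NULL` leaves the RNG alone).
#' @return A [genome] with chromosomes `chr1`, `chr2`, ...
#' @export
random_genome <- function(length, n_chroms = 1L, seed = NULL) {
  stopifnot(length >= n_chroms, n_chroms >= 1)
  with_seed(seed, {
    per <- rep(length %/% n_chroms, n_chroms)
    per[n_chroms] <- per[n_chroms] + length %% n_chroms
    seqs <- vapply(per, function(n) {
      paste(sample(BASES, n, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(n_chroms))
    genome(seqs)
  })
}

#' Parameters for breed-divergence simulation
#'
#' @param snp_rate Background substitution probability per base.
#' @param het_fraction Fraction of background variant sites that are
#'   heterozygous (variable-region substitutions are always homozygous).
#' @param n_hvr Number of planted highly variable clusters.
#' @param hvr_length_range Length range (min, max) of planted clusters, bases;
#'   minimum 3 so every cluster can carry a detectable run.
#' @param hvr_divergence Per-base substitution probability inside a cluster,
#'   beyond the defining run. Every planted cluster carries one run of three
#'   consecutive substitutions (what defines a highly variable region);
#'   additional substitutions are drawn per base at this rate and thinned to
#'   a minimum 8 bp separation so that planted variation stays anchorable by
#'   reads within the mapper's mismatch budget.
#' @param seed RNG seed.
#' @return A `breed_sim_params` list.
#' @export
breed_sim_params <- function(snp_rate = 0.005, het_fraction = 0.2,
                             n_hvr = 30L, hvr_length_range = c(9L, 36L),
                             hvr_divergence = 0.1, seed = NULL) {
  stopifnot(snp_rate >= 0, snp_rate <= 1,
            het_fraction >= 0, het_fraction <= 1,
            hvr_divergence >= 0, hvr_divergence <= 1,
            n_hvr >= 0, length(hvr_length_range) == 2,
            hvr_length_range[1] >= 3,
            hvr_length_range[1] <= hvr_length_range[2])
  structure(list(snp_rate = snp_rate, het_fraction = het_fraction,
                 n_hvr = as.integer(n_hvr),
                 hvr_length_range = as.integer(hvr_length_range),
                 hvr_divergence = hvr_divergence, seed = seed),
            class = "breed_sim_params")
}

# Substitution mask for one planted cluster: a defining run of exactly
# three consecutive substitutions, plus extras at rate `rate` thinned to a
# minimum separation of `min_gap` bases from the run and from each other.
# Unthinned Bernoulli placement would plant runs of four or more tightly
# packed substitutions, which no read within the mapper's mismatch budget
# can anchor across - a genuine limit of substitution-based reference
# updating that the generator does not manufacture on purpose.
hvr_mask <- function(len, rate, min_gap = 8L) {
  mask <- logical(len)
  run_start <- sample.int(len - 2L, 1L)
  kept <- run_start:(run_start + 2L)
  mask[kept] <- TRUE
  cand <- which(stats::runif(len) < rate & !mask)
  for (i in cand) {
    if (all(abs(i - kept) >= min_gap)) {
      mask[i] <- TRUE
      kept <- c(kept, i)
    }
  }
  mask
}

#' Simulate a diverged breed genome with a truth set
#'
#' Plants background SNPs (a fraction heterozygous), plus non-overlapping
#' highly variable clusters of homozygous substitutions, into a reference.
#' The returned truth "breed genome" is the alternate-carrying haplotype
#' (every planted variant applied); heterozygous sites are marked in the
#' truth callset, and the reference-carrying haplotype is recovered by
#' reverting het sites.
#'
#' @param reference A [genome].
#' @param params A [breed_sim_params()] list.
#' @return A `truth_set` list with elements `breed` (genome), `truth_calls`
#'   (a [callset]), `planted_hvrs` (tibble `chrom`, `start`, `end`; 0-based
#'   half-open) and `params`.
#' @export
simulate_breed <- function(reference, params = breed_sim_params()) {
  reference <- as_genome(reference)
  with_seed(params$seed, {
    lens <- genome_lengths(reference)
    chroms <- names(lens)
    # distribute clusters across chromosomes proportional to length
    hvr_chrom <- if (params$n_hvr > 0) {
      sample(chroms, params$n_hvr, replace = TRUE, prob = lens)
    } else character()
    calls <- list()
    hvrs <- list()
    breed_seqs <- character(length(chroms))
    names(breed_seqs) <- chroms
    for (ch in chroms) {
      chars <- chrom_chars(reference, ch)
      L <- length(chars)
      in_hvr <- logical(L)
      margin <- if (L > 500L) 150L else 0L
      # place this chromosome's clusters without overlap
      n_here <- sum(hvr_chrom == ch)
      placed <- 0L
      tries <- 0L
      while (placed < n_here) {
        if (tries > 1000L * n_here) {
          stop("could not place ", n_here, " non-overlapping variable regions on ",
               ch, "; reduce n_hvr or their lengths")
        }
        tries <- tries + 1L
        len <- sample(params$hvr_length_range[1]:params$hvr_length_range[2], 1L)
        if (L - 2L * margin < len) next
        start <- sample.int(L - 2L * margin - len + 1L, 1L) + margin - 1L  # 0-based
        span <- (start + 1L):(start + len)
        if (any(in_hvr[span]) || any(chars[span] == "N")) next
        in_hvr[span] <- TRUE
        # keep background SNPs out of an 8 bp buffer around the cluster
        buffer <- max(1L, start - 7L):min(L, start + len + 8L)
        in_hvr[buffer] <- TRUE
        mask <- hvr_mask(len, params$hvr_divergence)
        pos <- span[mask]  # 1-based positions
        if (length(pos) > 0) {
          alt <- vapply(chars[pos], function(b) sample(setdiff(BASES, b), 1L), character(1))
          calls[[length(calls) + 1L]] <- tibble::tibble(
            chrom = ch, pos = pos, ref = chars[pos], alt = alt, genotype = "hom_alt")
        }
        hvrs[[length(hvrs) + 1L]] <- tibble::tibble(chrom = ch, start = start,
                                                    end = start + len)
        placed <- placed + 1L
      }
      # background SNPs outside clusters and away from N
      bg <- which(!in_hvr & chars != "N")
      hit <- bg[stats::runif(length(bg)) < params$snp_rate]
      if (length(hit) > 0) {
        alt <- vapply(chars[hit], function(b) sample(setdiff(BASES, b), 1L), character(1))
        het <- stats::runif(length(hit)) < params$het_fraction
        calls[[length(calls) + 1L]] <- tibble::tibble(
          chrom = ch, pos = hit, ref = chars[hit], alt = alt,
          genotype = ifelse(het, "het", "hom_alt"))
      }
      breed_seqs[ch] <- chars_to_chrom(chars)
    }
    truth <- dplyr::bind_rows(calls)
    if (nrow(truth) == 0) {
      truth <- tibble::tibble(chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              genotype = character())
    }
    truth <- callset(truth$chrom, truth$pos, truth$ref, truth$alt, truth$genotype)
    truth <- sort_callset(truth, chroms)
    # breed haplotype: every planted variant applied
    breed <- as_genome(breed_seqs)
    if (nrow(truth) > 0) {
      breed <- apply_substitutions(breed, truth, hom_only = FALSE)$genome
    }
    hvr_tbl <- dplyr::bind_rows(hvrs)
    if (nrow(hvr_tbl) == 0) {
      hvr_tbl <- tibble::tibble(chrom = character(), start = integer(), end = integer())
    }
    hvr_tbl <- dplyr::arrange(hvr_tbl, match(.data$chrom, chroms), .data$start)
    structure(list(breed = breed, truth_calls = truth, planted_hvrs = hvr_tbl,
                   reference = reference, params = params),
              class = "truth_set")
  })
}

#' Parameters for shotgun read simulation
#'
#' @param read_length Read length in bases.
#' @param coverage Mean sequencing depth (x).
#' @param error_rate Per-base miscall probability (must be below 0.25).
#' @param paired Emit read pairs (mapped independently downstream).
#' @param seed RNG seed.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(read_length = 50L, coverage = 30, error_rate = 0,
                            paired = FALSE, seed = NULL) {
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 0.25, read_length >= 1)
  structure(list(read_length = as.integer(read_length), coverage = coverage,
                 error_rate = error_rate, paired = paired, seed = seed),
            class = "read_sim_params")
}

#' Simulate error-bearing shotgun reads from a simulated breed
#'
#' Read start positions are uniform over each chromosome (chromosomes chosen
#' proportional to length); each read draws one of the two haplotypes with
#' probability 1/2 (het sites differ between haplotypes), a random strand,
#' and independent per-base errors. The number of reads is
#' `round(coverage * genome_length / read_length)`.
#'
#' @param truth A `truth_set` from [simulate_breed()] (or a [genome] for
#'   haplotype-free simulation).
#' @param params A [read_sim_params()] list.
#' @return A tibble of reads (`id`, `seq`, `qual`).
#' @export
simulate_reads <- function(truth, params = read_sim_params()) {
  if (is_genome(truth)) {
    hap1 <- truth
    hap2 <- truth
  } else {
    stopifnot(inherits(truth, "truth_set"))
    hap1 <- truth$breed
    het <- dplyr::filter(truth$truth_calls, .data$genotype == "het")
    hap2 <- if (nrow(het) > 0) {
      rev_calls <- callset(het$chrom, het$pos, ref = het$alt, alt = het$ref,
                           genotype = "hom_alt")
      apply_substitutions(hap1, rev_calls, hom_only = TRUE)$genome
    } else hap1
  }
  lens <- genome_lengths(hap1)
  L <- params$read_length
  if (L > min(lens)) stop("read_length exceeds the shortest chromosome")
  G <- sum(lens)
  n_reads <- max(1L, as.integer(round(params$coverage * G / L)))
  if (params$paired && n_reads %% 2L == 1L) n_reads <- n_reads + 1L
  with_seed(params$seed, {
    chrom_i <- sample.int(length(lens), n_reads, replace = TRUE,
                          prob = lens - L + 1)
    start <- vapply(chrom_i, function(i) sample.int(lens[i] - L + 1L, 1L),
                    integer(1))  # 1-based
    hap <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    h1 <- unclass(hap1)
    h2 <- unclass(hap2)
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      src <- if (hap[i]) h1 else h2
      seqs[i] <- substr(src[[chrom_i[i]]], start[i], start[i] + L - 1L)
    }
    if (params$error_rate > 0) {
      n_err <- stats::rbinom(n_reads, L, params$error_rate)
      for (i in which(n_err > 0)) {
        cs <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        at <- sample.int(L, n_err[i])
        cs[at] <- vapply(cs[at], function(b) {
          sample(setdiff(BASES, b), 1L)
        }, character(1))
        seqs[i] <- paste(cs, collapse = "")
      }
    }
    flip <- strand == "-"
    seqs[flip] <- revcomp(seqs[flip])
    tibble::tibble(
      id = sprintf("read%06d", seq_len(n_reads)),
      seq = seqs,
      qual = strrep("I", L)
    )
  })
}

#' Downsample a read pool to a target coverage
#'
#' Uniform random subset without replacement of size
#' `round(target_coverage * genome_length / read_length)`, deterministic
#' given `seed`; original read order is preserved.
#'
#' @param reads Read tibble.
#' @param target_coverage Desired mean depth (x).
#' @param genome_length Total reference length in bases.
#' @param read_length Read length in bases.
#' @param seed RNG seed.
#' @return A subset of `reads`.
#' @export
downsample_reads <- function(reads, target_coverage, genome_length,
                             read_length, seed = NULL) {
  n <- as.integer(round(target_coverage * genome_length / read_length))
  if (n > nrow(reads)) {
    stop("requested ", n, " reads at ", target_coverage,
         "x but only ", nrow(reads), " available")
  }
  with_seed(seed, reads[sort(sample.int(nrow(reads), n)), , drop = FALSE])
}
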
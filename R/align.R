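#' Mapper parameters
#'
#' Deterministic k-mer seed-and-extend mapping with ungapped (Hamming)
#' scoring. `k = 17` keeps random seed hits rare at desk-scale genome sizes;
#' `max_mismatches = 3` per 100 bp read tolerates simulated divergence while
#' preserving the consecutive-mismatch ("unmappable variable region") effect
#' that the iterative strategy exists to fix. Note the seed guarantee: a
#' best hit with `m` mismatches is always found when
#' `floor(read_length / k) > m`.
#'
#' @param k Seed length (>= 8).
#' @param max_mismatches Maximum Hamming distance for a mapped read.
#' @param require_unique_best Leave a read unmapped when two candidate loci
#'   tie at the best score (otherwise the lowest `(chrom, pos, strand)` wins).
#' @return A `mapper_params` list.
#' @export
mapper_params <- function(k = 17L, max_mismatches = 3L,
                          require_unique_best = TRUE) {
  stopifnot(k >= 8, max_mismatches >= 0)
  structure(list(k = as.integer(k), max_mismatches = as.integer(max_mismatches),
                 require_unique_best = isTRUE(require_unique_best)),
            class = "mapper_params")
}

#' Build a k-mer index over a genome
#'
#' Every position of every k-mer not containing N is retrievable with
#' [kmer_hits()]; reverse-strand mapping is handled at query time by also
#' seeding the read's reverse complement.
#'
#' @param genome A [genome].
#' @param k Seed length.
#' @return A `kmer_index` object.
#' @export
build_index <- function(genome, k = 17L) {
  genome <- as_genome(genome)
  k <- as.integer(k)
  if (k > min(genome_lengths(genome))) {
    stop("k = ", k, " exceeds the shortest chromosome")
  }
  structure(list(ptr = cpp_index_build(names(unclass(genome)), unclass(genome), k),
                 k = k, genome = genome),
            class = "kmer_index")
}

# rebuild the external pointer if it did not survive serialization
index_ptr <- function(index) {
  k <- tryCatch(cpp_index_k(index$ptr), error = function(e) -1L)
  if (!identical(k, index$k)) {
    index$ptr <- cpp_index_build(names(unclass(index$genome)),
                                 unclass(index$genome), index$k)
  }
  index
}

#' @rdname build_index
#' @param index A `kmer_index`.
#' @param kmer A length-`k` string.
#' @return `kmer_hits()` returns a tibble with columns `chrom` and `pos`
#'   (0-based) of every exact occurrence.
#' @export
kmer_hits <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"), nchar(kmer) == index$k)
  index <- index_ptr(index)
  hit <- cpp_index_query(index$ptr, toupper(kmer))
  tibble::tibble(chrom = names(unclass(index$genome))[hit$chrom_i],
                 pos = as.integer(hit$pos))
}

#' Map reads to an indexed genome
#'
#' Candidate loci are gathered from every seed hit of every read k-mer on
#' both strands, then scored by full-length Hamming distance (no gaps). A
#' read is mapped iff its best score is at most `max_mismatches`. The result
#' has one row per read: `read_id`, `chrom`, `pos` (0-based leftmost),
#' `strand`, `n_mismatches`, `mapped`, and `seq` (reference-forward oriented
#' for mapped reads, as-read otherwise).
#'
#' @param reads Read tibble (`id`, `seq`) or a single read for `map_read()`.
#' @param index A `kmer_index` from [build_index()] (or a [genome], indexed
#'   on the fly).
#' @param params A [mapper_params()] list.
#' @return An alignment tibble.
#' @export
map_reads <- function(reads, index, params = mapper_params()) {
  if (is_genome(index) || is.character(index)) {
    index <- build_index(index, params$k)
  }
  stopifnot(inherits(index, "kmer_index"))
  if (index$k != params$k) {
    stop("index was built with k = ", index$k, " but params$k = ", params$k)
  }
  index <- index_ptr(index)
  if (nrow(reads) == 0) {
    return(tibble::tibble(read_id = character(), chrom = character(),
                          pos = integer(), strand = character(),
                          n_mismatches = integer(), mapped = logical(),
                          seq = character()))
  }
  seqs <- toupper(reads$seq)
  res <- cpp_map_reads(index$ptr, reads$id, seqs,
                       params$max_mismatches, params$require_unique_best)
  out <- tibble::as_tibble(res)
  out$seq <- ifelse(out$mapped & out$strand == "-", revcomp(seqs), seqs)
  out
}

#' @rdname map_reads
#' @param read A single read: a list/row with `id` and `seq` (or a bare
#'   sequence string).
#' @export
map_read <- function(read, index, params = mapper_params()) {
  if (is.character(read)) read <- list(id = "read", seq = read)
  map_reads(tibble::tibble(id = read$id, seq = read$seq), index, params)
}

#' Mapping rate
#'
#' The ratio of mapped reads to total reads.
#'
#' @param alignments Alignment tibble.
#' @return A fraction in `[0, 1]`.
#' @export
mapping_rate <- function(alignments) {
  if (nrow(alignments) == 0) stop("mapping_rate needs at least one record")
  mean(alignments$mapped)
}

#' Coverage ratio
#'
#' The proportion of reference positions covered by at least one mapped
#' read.
#'
#' @param alignments Alignment tibble.
#' @param genome The reference [genome].
#' @return A fraction in `[0, 1]`.
#' @export
coverage_ratio <- function(alignments, genome) {
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  a <- alignments[alignments$mapped, , drop = FALSE]
  covered <- 0
  for (ci in seq_along(lens)) {
    ch <- names(lens)[ci]
    rows <- a$chrom == ch
    if (!any(rows)) next
    L <- lens[ci]
    starts <- a$pos[rows] + 1L
    ends <- pmin(a$pos[rows] + nchar(a$seq[rows]), L)
    delta <- tabulate(starts, nbins = L + 1L) -
      tabulate(ends + 1L, nbins = L + 1L)
    covered <- covered + sum(cumsum(delta)[1:L] > 0)
  }
  covered / sum(lens)
}
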
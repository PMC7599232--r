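#' Substitute called alleles into a reference
#'
#' SNP-only, coordinate-preserving substitution: each eligible call's
#' position is set to its alternate base. Eligible calls are
#' homozygous-alternate SNPs by default; with `hom_only = FALSE`
#' heterozygous SNPs are substituted too (which reproduces the round-to-round
#' allele flip-flop that makes het substitution inadvisable). Every call's
#' `ref` must match the genome at its position - a mismatch is a hard error,
#' the designed signal that a callset belongs to exactly one round. N bases
#' are never substituted into.
#'
#' @param genome A [genome].
#' @param calls A [callset].
#' @param hom_only Substitute homozygous-alternate calls only (default).
#' @param round_index Recorded in the substitution log.
#' @return A list with `genome` (new [genome], identical shape) and `log`
#'   (tibble `chrom, pos, old_base, new_base, round`).
#' @export
apply_substitutions <- function(genome, calls, hom_only = TRUE, round_index = 1L) {
  genome <- as_genome(genome)
  chroms <- names(unclass(genome))
  eligible <- calls$type == "snp" &
    (calls$genotype == "hom_alt" | (!hom_only & calls$genotype == "het"))
  todo <- calls[eligible, , drop = FALSE]
  bad_chrom <- setdiff(unique(calls$chrom), chroms)
  if (length(bad_chrom) > 0) {
    stop("callset names unknown chromosome: ", bad_chrom[1])
  }
  seqs <- unclass(genome)
  logs <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    rows <- todo[todo$chrom == chroms[ci], , drop = FALSE]
    if (nrow(rows) == 0) next
    if (anyDuplicated(rows$pos)) {
      stop("duplicate call position at ", chroms[ci], ":",
           rows$pos[duplicated(rows$pos)][1])
    }
    chars <- strsplit(seqs[[ci]], "", fixed = TRUE)[[1]]
    if (any(rows$pos < 1 | rows$pos > length(chars))) {
      stop("call position out of bounds on ", chroms[ci])
    }
    have <- chars[rows$pos]
    if (any(have == "N")) {
      stop("refusing to substitute into N at ", chroms[ci], ":",
           rows$pos[have == "N"][1])
    }
    mism <- have != rows$ref
    if (any(mism)) {
      i <- which(mism)[1]
      stop("reference mismatch at ", chroms[ci], ":", rows$pos[i],
           " (genome has ", have[i], ", call says ", rows$ref[i],
           ") - callset and reference are out of sync")
    }
    chars[rows$pos] <- rows$alt
    seqs[ci] <- paste(chars, collapse = "")
    logs[[ci]] <- tibble::tibble(chrom = chroms[ci], pos = rows$pos,
                                 old_base = rows$ref, new_base = rows$alt,
                                 round = as.integer(round_index))
  }
  log <- dplyr::bind_rows(logs)
  if (nrow(log) == 0) {
    log <- tibble::tibble(chrom = character(), pos = integer(),
                          old_base = character(), new_base = character(),
                          round = integer())
  }
  list(genome = structure(seqs, class = "genome"), log = log)
}

# shared shape check for positional genome comparisons
check_same_shape <- function(a, b) {
  la <- genome_lengths(a)
  lb <- genome_lengths(b)
  if (!identical(names(la), names(lb)) || !identical(unname(la), unname(lb))) {
    stop("genomes differ in chromosome names or lengths")
  }
  la
}

#' Positional differences between two same-shape genomes
#'
#' Every mismatching position, sorted; positions where either base is N are
#' excluded (assembly gaps are not variation).
#'
#' @param a,b [genome]s with identical chromosome names and lengths.
#' @return A tibble `chrom, pos` (1-based), `base_a`, `base_b`.
#' @export
diff_genomes <- function(a, b) {
  a <- as_genome(a)
  b <- as_genome(b)
  lens <- check_same_shape(a, b)
  out <- vector("list", length(lens))
  for (ci in seq_along(lens)) {
    ra <- charToRaw(unclass(a)[[ci]])
    rb <- charToRaw(unclass(b)[[ci]])
    n <- charToRaw("N")
    idx <- which(ra != rb & ra != n & rb != n)
    if (length(idx) == 0) next
    out[[ci]] <- tibble::tibble(
      chrom = names(lens)[ci], pos = idx,
      base_a = strsplit(rawToChar(ra[idx]), "")[[1]],
      base_b = strsplit(rawToChar(rb[idx]), "")[[1]]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(chrom = character(), pos = integer(),
                          base_a = character(), base_b = character())
  }
  res
}
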
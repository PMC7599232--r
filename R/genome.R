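#' Genome objects
#'
#' A genome is an ordered, named set of chromosome sequences over the
#' alphabet `{A, C, G, T, N}`, stored as a named character vector with class
#' `"genome"`. Chromosome names must be unique and non-empty; lowercase input
#' is uppercased on construction. All per-site coordinates in this package
#' are 1-based (VCF convention) and all intervals are 0-based half-open
#' (BED convention); conversion happens only at format boundaries.
#'
#' @param sequences Named character vector of chromosome sequences.
#' @return An object of class `genome`.
#' @examples
#' g <- genome(c(chr1 = "acgtACGT"))
#' genome_lengths(g)
#' @export
genome <- function(sequences) {
  if (length(sequences) == 0) stop("a genome needs at least one chromosome")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("all chromosomes must be named with non-empty names")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name: ", nm[duplicated(nm)][1])
  }
  seqs <- toupper(as.character(sequences))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for chromosome: ", nm[!nzchar(seqs)][1])
  }
  bad <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop("illegal characters (outside A/C/G/T/N) in chromosome: ", nm[bad][1])
  }
  names(seqs) <- nm
  structure(seqs, class = "genome")
}

#' @rdname genome
#' @param x Object to convert or test.
#' @export
as_genome <- function(x) {
  if (is_genome(x)) x else genome(x)
}

#' @rdname genome
#' @export
is_genome <- function(x) inherits(x, "genome")

#' @rdname genome
#' @export
genome_lengths <- function(x) {
  x <- as_genome(x)
  vapply(unclass(x), nchar, integer(1))
}

#' @export
print.genome <- function(x, ...) {
  len <- genome_lengths(x)
  cat("<genome> ", length(x), " chromosome(s), ",
      format(sum(len), big.mark = ","), " bp total\n", sep = "")
  for (i in seq_along(len)) {
    s <- unclass(x)[[i]]
    head <- substr(s, 1, 40)
    cat("  ", names(len)[i], " (", format(len[i], big.mark = ","), " bp): ",
        head, if (nchar(s) > 40) "..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
`[.genome` <- function(x, i) {
  structure(unclass(x)[i], class = "genome")
}

#' Reverse complement of a DNA string
#'
#' N stays N; input must be over `{A,C,G,T,N}` (case-insensitive).
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# split a chromosome string into a character vector of single bases
chrom_chars <- function(genome, chrom) {
  strsplit(unclass(genome)[[chrom]], "", fixed = TRUE)[[1]]
}

# rebuild a chromosome string from a character vector
chars_to_chrom <- function(chars) paste(chars, collapse = "")
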
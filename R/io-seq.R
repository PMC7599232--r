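#' Read and write FASTA genomes
#'
#' `read_fasta()` reads a (possibly wrapped) FASTA file into a [genome]
#' object; the record name is the header token before the first whitespace.
#' `write_fasta()` writes a genome wrapped at 60 columns, so
#' `write_fasta(read_fasta(f))` reproduces sequences byte-identically.
#'
#' @param path File path.
#' @param x A [genome] (or named character vector of sequences).
#' @return `read_fasta()` returns a [genome]; `write_fasta()` returns `path`
#'   invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # read as raw strings: the genome() constructor does the alphabet
  # validation, so illegal letters are a hard error naming the record
  # instead of being silently dropped
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- nm
  genome(seqs)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  x <- as_genome(x)
  ss <- Biostrings::DNAStringSet(unclass(x))
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = 60L)
  invisible(path)
}

#' Read and write FASTQ reads
#'
#' Reads are a tibble with columns `id`, `seq` and `qual` (per-base quality
#' string, same length as `seq`). Four-line FASTQ records only; a truncated
#' trailing record is an error naming the record index.
#'
#' @param path File path.
#' @param reads Tibble with columns `id`, `seq`, `qual` (`qual` may be `NA`,
#'   written as constant `"I"`).
#' @return `read_fastq()` returns a tibble of reads; `write_fastq()` returns
#'   `path` invisibly.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  while (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ record at record index ", length(lines) %/% 4 + 1,
         " in ", path)
  }
  n <- length(lines) %/% 4
  if (n == 0) {
    return(tibble::tibble(id = character(), seq = character(), qual = character()))
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  seq <- toupper(lines[seq(2, length(lines), by = 4)])
  qual <- lines[seq(4, length(lines), by = 4)]
  if (any(!startsWith(hdr, "@"))) {
    stop("malformed FASTQ header at record index ", which(!startsWith(hdr, "@"))[1])
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0) {
    stop("sequence/quality length mismatch at record index ", bad[1])
  }
  tibble::tibble(
    id = sub("\\s.*$", "", substring(hdr, 2)),
    seq = seq,
    qual = qual
  )
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) reads$qual else NA_character_
  qual <- ifelse(is.na(qual),
                 vapply(nchar(reads$seq), function(n) strrep("I", n), character(1)),
                 qual)
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), by = 4)] <- reads$seq
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- qual
  writeLines(out, path)
  invisible(path)
}
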
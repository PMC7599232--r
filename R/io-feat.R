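#' Read gene/CDS annotation from a GTF file
#'
#' Ensembl-dialect GTF (1-based, inclusive). Only `gene` and `CDS` features
#' are kept; the number of skipped features of other types is reported with
#' a message. Intervals are converted to the package-internal 0-based
#' half-open convention.
#'
#' @param path GTF file path.
#' @return A tibble of features with columns `chrom`, `start`, `end`
#'   (0-based half-open), `kind` (`"gene"` or `"CDS"`) and `feature_id`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  data_i <- which(!startsWith(lines, "#") & nzchar(lines))
  feats <- vector("list", length(data_i))
  n_skipped <- 0L
  for (j in seq_along(data_i)) {
    ln <- data_i[j]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stop("malformed GTF (fewer than 9 columns) at line ", ln)
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1 || end < start) {
      stop("malformed GTF coordinates at line ", ln)
    }
    if (!f[3] %in% c("gene", "CDS")) {
      n_skipped <- n_skipped + 1L
      next
    }
    id <- sub('.*gene_id "([^"]+)".*', "\\1", f[9])
    if (identical(id, f[9])) id <- paste0("feature_", ln)
    feats[[j]] <- tibble::tibble(
      chrom = f[1], start = start - 1L, end = end,
      kind = f[3], feature_id = id
    )
  }
  if (n_skipped > 0) {
    message("read_gtf: skipped ", n_skipped, " feature(s) not in {gene, CDS}")
  }
  out <- dplyr::bind_rows(feats)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          kind = character(), feature_id = character())
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Read and write BED intervals
#'
#' Three columns plus an optional name, 0-based half-open, deterministic
#' output. Comment lines starting with `#` are skipped on read.
#'
#' @param path File path.
#' @param regions Tibble with columns `chrom`, `start`, `end` and optionally
#'   `name`.
#' @return `read_bed()` returns a tibble; `write_bed()` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) stop("malformed BED line ", which(nf < 3)[1])
  start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED coordinates at line ", which(is.na(start) | is.na(end))[1])
  }
  tibble::tibble(
    chrom = vapply(parts, `[`, character(1), 1),
    start = start, end = end,
    name = ifelse(nf >= 4, vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, character(1)), NA_character_)
  )
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  name <- if ("name" %in% names(regions)) regions$name else NULL
  lines <- if (is.null(name) || all(is.na(name))) {
    paste(regions$chrom, regions$start, regions$end, sep = "\t")
  } else {
    paste(regions$chrom, regions$start, regions$end, name, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write alignments as SAM
#'
#' Minimal dialect: `@HD`/`@SQ` header lines, columns 1-11 and the `NM` tag.
#' Flags used are 0 (forward), 16 (reverse) and 4 (unmapped); CIGAR is always
#' full-length `M` for mapped reads (ungapped alignment). The `seq` column
#' holds the reference-forward oriented sequence, as SAM requires.
#'
#' @param alignments Alignment tibble as produced by [map_reads()].
#' @param genome The reference [genome] (for `@SQ` header lines).
#' @param path File path.
#' @return `read_sam()` returns an alignment tibble; `write_sam()` returns
#'   `path` invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  genome <- as_genome(genome)
  len <- genome_lengths(genome)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(len), "\tLN:", len))
  a <- alignments
  flag <- ifelse(!a$mapped, 4L, ifelse(a$strand == "-", 16L, 0L))
  rname <- ifelse(a$mapped, a$chrom, "*")
  pos <- ifelse(a$mapped, a$pos + 1L, 0L)
  mapq <- ifelse(a$mapped, 60L, 0L)
  cigar <- ifelse(a$mapped, paste0(nchar(a$seq), "M"), "*")
  body <- paste(a$read_id, flag, rname, pos, mapq, cigar, "*", 0L, 0L,
                a$seq, "*", sep = "\t")
  body <- ifelse(a$mapped, paste0(body, "\tNM:i:", a$n_mismatches), body)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble::tibble(read_id = character(), chrom = character(),
                          pos = integer(), strand = character(),
                          n_mismatches = integer(), mapped = logical(),
                          seq = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11)) stop("malformed SAM line ", which(nf < 11)[1])
  get <- function(i) vapply(parts, `[`, character(1), i)
  flag <- as.integer(get(2))
  mapped <- bitwAnd(flag, 4L) == 0L
  nm <- vapply(parts, function(p) {
    hit <- grep("^NM:i:", p[-(1:11)], value = TRUE)
    if (length(hit) > 0) as.integer(sub("NM:i:", "", hit[1])) else NA_integer_
  }, integer(1))
  tibble::tibble(
    read_id = get(1),
    chrom = ifelse(mapped, get(3), NA_character_),
    pos = ifelse(mapped, as.integer(get(4)) - 1L, NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"), NA_character_),
    n_mismatches = ifelse(mapped, nm, NA_integer_),
    mapped = mapped,
    seq = get(10)
  )
}
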
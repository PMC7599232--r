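#' Detect highly variable regions between two same-shape genomes
#'
#' A highly variable region (HVR) is a maximal run of at least `min_run`
#' consecutive mismatching positions between the original and the
#' alternative reference. N positions break runs without counting as
#' mismatches. Valid because substitution is SNP-only and
#' coordinate-preserving, so the comparison is positional.
#'
#' @param original,alternative [genome]s with identical shape.
#' @param min_run Minimum run length (default 3, the defining minimum).
#' @return A tibble `chrom, start, end, length` (0-based half-open), sorted.
#' @export
find_hvr <- function(original, alternative, min_run = 3L) {
  original <- as_genome(original)
  alternative <- as_genome(alternative)
  lens <- check_same_shape(original, alternative)
  out <- vector("list", length(lens))
  for (ci in seq_along(lens)) {
    ra <- charToRaw(unclass(original)[[ci]])
    rb <- charToRaw(unclass(alternative)[[ci]])
    n <- charToRaw("N")
    mism <- ra != rb & ra != n & rb != n
    r <- rle(as.vector(mism))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- r$values & r$lengths >= min_run
    if (!any(hit)) next
    out[[ci]] <- tibble::tibble(
      chrom = names(lens)[ci],
      start = starts[hit] - 1L,   # 0-based half-open
      end = ends[hit],
      length = r$lengths[hit]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), length = integer())
  }
  res
}

#' Annotate highly variable regions with gene/CDS overlap
#'
#' A region overlaps a feature iff their half-open intervals share at least
#' one base.
#'
#' @param regions HVR tibble from [find_hvr()].
#' @param features Annotation tibble from [read_gtf()] (columns `chrom`,
#'   `start`, `end`, `kind`).
#' @return `regions` with logical columns `overlaps_gene` and `overlaps_cds`.
#' @export
annotate_hvr <- function(regions, features) {
  overlap_any <- function(kind) {
    f <- features[features$kind == kind, , drop = FALSE]
    vapply(seq_len(nrow(regions)), function(i) {
      sel <- f$chrom == regions$chrom[i] &
        f$start < regions$end[i] & regions$start[i] < f$end
      any(sel)
    }, logical(1))
  }
  regions$overlaps_gene <- overlap_any("gene")
  regions$overlaps_cds <- overlap_any("CDS")
  regions
}

#' Summarize annotated highly variable regions
#'
#' Per-chromosome and total counts of HVRs and of HVRs overlapping genes and
#' CDSs, with overall fractions.
#'
#' @param regions Annotated HVR tibble from [annotate_hvr()].
#' @return A tibble with one row per chromosome plus a `total` row, columns
#'   `chrom, n_hvr, n_gene_overlap, n_cds_overlap, frac_gene, frac_cds`.
#' @export
hvr_summary <- function(regions) {
  per <- regions |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n_hvr = dplyr::n(),
                     n_gene_overlap = sum(.data$overlaps_gene),
                     n_cds_overlap = sum(.data$overlaps_cds),
                     .groups = "drop")
  tot <- tibble::tibble(chrom = "total", n_hvr = nrow(regions),
                        n_gene_overlap = sum(regions$overlaps_gene),
                        n_cds_overlap = sum(regions$overlaps_cds))
  out <- dplyr::bind_rows(per, tot)
  out$frac_gene <- ifelse(out$n_hvr > 0, out$n_gene_overlap / out$n_hvr, NA_real_)
  out$frac_cds <- ifelse(out$n_hvr > 0, out$n_cds_overlap / out$n_hvr, NA_real_)
  out
}

#' Genome similarity
#'
#' The number of matched bases (both non-N) divided by the total genome
#' size.
#'
#' @param a,b [genome]s with identical shape.
#' @return A fraction in `[0, 1]`.
#' @export
genome_similarity <- function(a, b) {
  a <- as_genome(a)
  b <- as_genome(b)
  lens <- check_same_shape(a, b)
  matched <- 0
  for (ci in seq_along(lens)) {
    ra <- charToRaw(unclass(a)[[ci]])
    rb <- charToRaw(unclass(b)[[ci]])
    n <- charToRaw("N")
    matched <- matched + sum(ra == rb & ra != n)
  }
  matched / sum(lens)
}
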
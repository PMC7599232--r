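#' Callsets
#'
#' A callset is a tibble of per-locus variant calls with columns
#' `chrom`, `pos` (1-based), `ref`, `alt`, `genotype` (`"hom_alt"` or
#' `"het"`), `depth`, `alt_fraction` and `type` (`"snp"` or `"other"`).
#' Only single-base `"snp"` records are substitutable into a reference;
#' non-SNP records survive VCF round-trips but are never applied.
#'
#' @param chrom,pos,ref,alt,genotype,depth,alt_fraction,type Column vectors.
#' @return A callset tibble.
#' @export
callset <- function(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), genotype = character(),
                    depth = NA_integer_, alt_fraction = NA_real_,
                    type = NULL) {
  if (is.null(type)) {
    type <- ifelse(nchar(ref) == 1 & nchar(alt) == 1 &
                     ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T"),
                   "snp", "other")
  }
  tibble::tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    genotype = as.character(genotype),
    depth = as.integer(depth), alt_fraction = as.numeric(alt_fraction),
    type = as.character(type)
  )
}

# sort a callset by (chrom, pos) in the chromosome order given (or alphabetical)
sort_callset <- function(calls, chrom_levels = NULL) {
  if (is.null(chrom_levels)) chrom_levels <- sort(unique(calls$chrom))
  calls[order(match(calls$chrom, chrom_levels), calls$pos), , drop = FALSE]
}

#' Read and write SNP callsets in VCF 4.2
#'
#' The dialect is deliberately narrow: one sample, a `GT` entry in the
#' FORMAT/sample columns, genotype `1/1` (or `1|1`) read as homozygous-alternate
#' and `0/1`, `1/0` (or phased forms) as heterozygous. Multi-allelic records
#' and records without `GT` are hard errors. Indel records are read with
#' `type = "other"` and are never substituted. `write_vcf()` emits
#' deterministic plain text preserving CHROM/POS/REF/ALT/GT (and DP when
#' depth is known).
#'
#' @param path File path.
#' @param calls A [callset] tibble.
#' @param sample_name Sample column name to write.
#' @return `read_vcf()` returns a [callset]; `write_vcf()` returns `path`
#'   invisibly.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  body <- any(!startsWith(readLines(path, warn = FALSE), "#"))
  if (!body) return(callset())
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    i <- which(grepl(",", alt, fixed = TRUE))[1]
    stop("multi-allelic record not supported at ", fix[i, "CHROM"], ":", fix[i, "POS"])
  }
  gt_mat <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                     error = function(e) NULL)
  if (is.null(gt_mat) || ncol(gt_mat) < 1) {
    stop("VCF has no GT field / sample column: ", path)
  }
  gt <- as.character(gt_mat[, 1])
  if (anyNA(gt)) {
    i <- which(is.na(gt))[1]
    stop("missing GT at ", fix[i, "CHROM"], ":", fix[i, "POS"])
  }
  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  genotype <- dplyr::case_when(
    gt_norm == "1/1" ~ "hom_alt",
    gt_norm %in% c("0/1", "1/0") ~ "het",
    TRUE ~ NA_character_
  )
  if (anyNA(genotype)) {
    i <- which(is.na(genotype))[1]
    stop("unsupported genotype '", gt[i], "' at ", fix[i, "CHROM"], ":", fix[i, "POS"])
  }
  dp_mat <- suppressWarnings(tryCatch(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
    error = function(e) NULL))
  depth <- if (is.null(dp_mat)) NA_integer_ else as.integer(dp_mat[, 1])
  callset(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt, genotype = genotype, depth = depth
  )
}

#' @rdname read_vcf
#' @export
write_vcf <- function(calls, path, sample_name = "sample") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=iterref",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  if (nrow(calls) > 0) {
    gt <- ifelse(calls$genotype == "hom_alt", "1/1", "0/1")
    has_dp <- !is.na(calls$depth)
    fmt <- ifelse(has_dp, "GT:DP", "GT")
    smp <- ifelse(has_dp, paste0(gt, ":", calls$depth), gt)
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", ".", fmt, smp, sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}
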
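#' Caller parameters
#'
#' Hard-cutoff pileup genotyping: at a position with depth at least
#' `min_depth` and exactly one non-reference allele observed, the allele
#' fraction `f` decides the genotype: `f >= hom_threshold` is a
#' homozygous-alternate call, `het_band[1] <= f < het_band[2]` a
#' heterozygous call, anything else no call.
#'
#' @param min_depth Minimum read depth.
#' @param hom_threshold Alt-fraction threshold for hom-alt.
#' @param het_band Alt-fraction interval `(low, high)` for het.
#' @return A `caller_params` list.
#' @export
caller_params <- function(min_depth = 3L, hom_threshold = 0.8,
                          het_band = c(0.2, 0.8)) {
  stopifnot(min_depth >= 1, het_band[1] > 0, het_band[1] < het_band[2],
            het_band[2] <= hom_threshold, hom_threshold <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 hom_threshold = hom_threshold, het_band = het_band),
            class = "caller_params")
}

#' Pileup-based SNP genotyping
#'
#' Counts bases from mapped, reference-forward oriented reads at every
#' reference position and emits SNP calls per [caller_params()]. Positions
#' where the reference is N, or where more than one distinct non-reference
#' allele is seen, are never called. Output is sorted by `(chrom, pos)` in
#' reference order.
#'
#' @param alignments Alignment tibble from [map_reads()] (or [read_sam()]).
#' @param genome The reference [genome] the alignments refer to.
#' @param params A [caller_params()] list.
#' @return A [callset] tibble.
#' @export
pileup_and_call <- function(alignments, genome, params = caller_params()) {
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  chroms <- names(lens)
  a <- alignments[alignments$mapped, , drop = FALSE]
  piles <- cpp_pileup(unname(lens), match(a$chrom, chroms), a$pos, a$seq)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    counts <- piles[[ci]]               # 5 x L: A, C, G, T, other
    depth <- colSums(counts)
    chars <- chrom_chars(genome, chroms[ci])
    ref_i <- match(chars, BASES)        # NA at N positions
    acgt <- counts[1:4, , drop = FALSE]
    # zero out the reference allele row position-wise
    keep <- which(depth >= params$min_depth & !is.na(ref_i))
    if (length(keep) == 0) next
    sub <- acgt[, keep, drop = FALSE]
    sub[cbind(ref_i[keep], seq_along(keep))] <- 0L
    n_alleles <- colSums(sub > 0)
    top <- apply(sub, 2, max)
    ok <- n_alleles == 1L
    if (!any(ok)) next
    pos <- keep[ok]
    alt_i <- max.col(t(sub[, ok, drop = FALSE]))
    f <- top[ok] / depth[pos]
    genotype <- rep(NA_character_, length(pos))
    genotype[f >= params$hom_threshold] <- "hom_alt"
    genotype[f >= params$het_band[1] & f < params$het_band[2]] <- "het"
    called <- !is.na(genotype)
    if (!any(called)) next
    out[[ci]] <- callset(
      chrom = chroms[ci], pos = pos[called], ref = chars[pos[called]],
      alt = BASES[alt_i[called]], genotype = genotype[called],
      depth = depth[pos][called], alt_fraction = f[called]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(callset())
  sort_callset(res, chroms)
}

#' Precision and sensitivity from benchmark counts
#'
#' `precision = TP / (TP + FP)`, `sensitivity = TP / (TP + FN)`; `NA` when
#' the denominator is zero.
#'
#' @param tp,fp,fn Counts.
#' @return A one-row tibble `tp, fp, fn, precision, sensitivity`.
#' @export
precision_sensitivity <- function(tp, fp, fn) {
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  )
}

#' Compare a callset against a gold standard
#'
#' A true positive is a called variant present in the gold standard with
#' matching `(chrom, pos, ref, alt)` and, when `genotype_aware` (the
#' default), the same genotype class; a called variant matching position and
#' alleles but not genotype counts as a false positive and leaves the gold
#' record a false negative. Both inputs must be sorted by `(chrom, pos)`.
#'
#' @param test,gold [callset] tibbles.
#' @param genotype_aware Require matching genotype class for a TP.
#' @return A one-row tibble `tp, fp, fn, precision, sensitivity`.
#' @export
compare_callsets <- function(test, gold, genotype_aware = TRUE) {
  check_sorted <- function(x, what) {
    if (nrow(x) < 2) return(invisible())
    o <- order(match(x$chrom, unique(x$chrom)), x$pos)
    if (!identical(o, seq_len(nrow(x)))) stop(what, " callset is not sorted by (chrom, pos)")
  }
  check_sorted(test, "test")
  check_sorted(gold, "gold")
  keys <- c("chrom", "pos", "ref", "alt", if (genotype_aware) "genotype")
  tp <- nrow(dplyr::inner_join(test[keys], gold[keys], by = keys))
  precision_sensitivity(tp = tp, fp = nrow(test) - tp, fn = nrow(gold) - tp)
}

#' Count variants in a callset
#'
#' @param calls A [callset].
#' @param type_filter One of `"all"`, `"snp"`, `"indel"`, `"hom"`, `"het"`.
#' @return An integer count.
#' @export
count_variants <- function(calls, type_filter = c("all", "snp", "indel", "hom", "het")) {
  type_filter <- match.arg(type_filter)
  switch(type_filter,
         all = nrow(calls),
         snp = sum(calls$type == "snp"),
         indel = sum(calls$type != "snp"),
         hom = sum(calls$genotype == "hom_alt"),
         het = sum(calls$genotype == "het"))
}
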
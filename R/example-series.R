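#' Published example series: Wuzhishan pig coverage titration
#'
#' Published SNP counts called from Wuzhishan (WZS) pig whole-genome
#' sequencing reads downsampled to 1-30x against the Sscrofa11.1 reference.
#' Useful for exercising the rising saturation fit on real numbers.
#'
#' @return A [curve_series()] of SNP count against coverage (x = 1..30).
#' @export
wzs_coverage_series <- function() {
  curve_series(
    x = 1:30,
    y_raw = c(1944247, 4712874, 6889545, 8395125, 9379364, 10055111,
              10493413, 10785210, 11057014, 11212461, 11384781, 11475145,
              11539920, 11653799, 11694650, 11782668, 11805726, 11827889,
              11898117, 11908403, 11970269, 11974123, 11978131, 12029145,
              12030019, 12075970, 12073458, 12071291, 12113790, 12108531)
  )
}

#' Published example series: Wuzhishan pig iteration counts
#'
#' Variant counts called in each of 30 map-call-substitute rounds for the
#' WZS individual used to build the alternative reference (round 1 is
#' against the original reference). The large round 1 to 2 drop and the
#' long flat tail are the signature of the iterative strategy; the falling
#' logistic fitted to these counts yields an optimal round count of 7 at
#' the 1e-4 slope threshold.
#'
#' @return A [curve_series()] of variant count against round (x = 1..30).
#' @export
wzs_iteration_series <- function() {
  curve_series(
    x = 1:30,
    y_raw = c(14311513, 3295192, 2766075, 2682333, 2663703, 2654321,
              2648887, 2646651, 2644442, 2643524, 2643077, 2642597,
              2642070, 2642098, 2642033, 2641897, 2641860, 2641655,
              2641151, 2641564, 2641376, 2641402, 2641172, 2641227,
              2641079, 2641212, 2640874, 2640890, 2641280, 2641270)
  )
}

#' Published rising logistic fits for five pig breeds
#'
#' The coverage-saturation fits (log2 SNP count against coverage) published
#' for the WZS, BMX, SZL, LD and DU pig breeds. Duroc (DU), the slowest to
#' saturate, drives the published 19x coverage recommendation.
#'
#' @return A named list of rising `logistic_fit` objects.
#' @export
pig_breed_coverage_fits <- function() {
  list(
    WZS = logistic_fit(23.48, 0.2202, 0.6047, "rising", r = 0.9954),
    BMX = logistic_fit(23.23, 0.2204, 0.6587, "rising", r = 0.9947),
    SZL = logistic_fit(23.25, 0.2057, 0.6595, "rising", r = 0.9953),
    LD  = logistic_fit(22.54, 0.2362, 0.6831, "rising", r = 0.9965),
    DU  = logistic_fit(22.02, 0.2063, 0.5551, "rising", r = 0.9479)
  )
}

#' Published falling logistic fit for the WZS iteration series
#'
#' The published fit of log2 variant count against iteration round for the
#' WZS pig: `y = 21.34 / (1 - 0.7039 exp(-1.9272 x))`.
#'
#' @return A falling `logistic_fit`.
#' @export
wzs_iteration_fit <- function() {
  logistic_fit(21.34, 0.7039, 1.9272, "falling", r = 0.9999)
}

#' Published benchmark counts for an FPGA and a CPU variant-calling workflow
#'
#' TP/FP/FN counts against the GIAB NA12878 gold standard for an
#' FPGA-accelerated workflow ("gtx") and the BWA-GATK best-practices
#' workflow ("gbp"), by variant type. Feed rows to
#' [precision_sensitivity()].
#'
#' @return A tibble `workflow, variant_type, tp, fp, fn`.
#' @export
variant_benchmark_counts <- function() {
  tibble::tribble(
    ~workflow, ~variant_type, ~tp,      ~fp,    ~fn,
    "gtx",     "snp",         3188714,  14706,  20601,
    "gtx",     "indel",       464578,   8711,   15999,
    "gbp",     "snp",         3177555,  9312,   31760,
    "gbp",     "indel",       469265,   6339,   11312
  )
}
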
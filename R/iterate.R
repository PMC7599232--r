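#' Configuration for the iterative reference-update loop
#'
#' @param max_rounds Maximum number of map-call-substitute rounds.
#' @param hom_only Substitute homozygous-alternate calls only (default;
#'   heterozygous substitution causes round-to-round allele flip-flop).
#' @param tau Tangent-slope magnitude threshold for the optimal round count.
#' @param mapper A [mapper_params()] list.
#' @param caller A [caller_params()] list.
#' @param log_base Log base for the saturation fit.
#' @param seed Seed recorded with the run (the loop itself is deterministic).
#' @return An `iteration_config` list.
#' @export
iteration_config <- function(max_rounds = 30L, hom_only = TRUE, tau = 1e-4,
                             mapper = mapper_params(), caller = caller_params(),
                             log_base = 2, seed = NULL) {
  stopifnot(max_rounds >= 2)
  structure(list(max_rounds = as.integer(max_rounds), hom_only = isTRUE(hom_only),
                 tau = tau, mapper = mapper, caller = caller,
                 log_base = log_base, seed = seed),
            class = "iteration_config")
}

#' Run the iterative alternative-reference strategy
#'
#' Round `r` maps all reads to the round `r - 1` reference, calls SNPs,
#' records metrics, and substitutes the eligible calls to produce the round
#' `r` reference. The loop stops early once a round makes no substitution
#' (further rounds would be identical). Afterwards a falling logistic is
#' fitted to the per-round variant counts and the optimal round count is
#' the tangent-slope threshold crossing; the reported final genome is the
#' reference after that round, not after the last.
#'
#' @param reference The starting [genome].
#' @param reads Read tibble (`id`, `seq`).
#' @param config An [iteration_config()].
#' @param truth_genome Optional truth genome; per-round similarity to it is
#'   then recorded.
#' @param eval_reads Optional independent read set mapped against each
#'   round's reference for evaluation only (never used for substitution).
#' @return An `iterref_result` list: `final` (genome at the optimal round),
#'   `trace` (per-round tibble), `fit` (`logistic_fit` or `NULL`),
#'   `optimal_n` (integer or `NA`), `genomes` (list of per-round genomes,
#'   element 1 being the input reference).
#' @export
run_iterations <- function(reference, reads, config = iteration_config(),
                           truth_genome = NULL, eval_reads = NULL) {
  reference <- as_genome(reference)
  if (nrow(reads) == 0) stop("no reads supplied")
  ref <- reference
  genomes <- list(reference)
  rows <- list()
  for (r in seq_len(config$max_rounds)) {
    idx <- build_index(ref, config$mapper$k)
    aln <- map_reads(reads, idx, config$mapper)
    calls <- pileup_and_call(aln, ref, config$caller)
    step <- apply_substitutions(ref, calls, hom_only = config$hom_only,
                                round_index = r)
    row <- tibble::tibble(
      round = r,
      variant_count = nrow(calls),
      hom_variant_count = count_variants(calls, "hom"),
      mapping_rate = mapping_rate(aln),
      coverage_ratio = coverage_ratio(aln, ref),
      n_substitutions = nrow(step$log)
    )
    if (!is.null(truth_genome)) {
      row$genome_similarity_to_truth <- genome_similarity(ref, truth_genome)
    }
    if (!is.null(eval_reads)) {
      row$eval_mapping_rate <- mapping_rate(map_reads(eval_reads, idx, config$mapper))
    }
    rows[[r]] <- row
    ref <- step$genome
    genomes[[r + 1L]] <- ref
    if (nrow(step$log) == 0) break
  }
  trace <- dplyr::bind_rows(rows)
  class(trace) <- c("iterref_trace", class(trace))

  fit <- NULL
  optimal_n <- NA_integer_
  pos <- trace[trace$variant_count > 0, c("round", "variant_count")]
  if (nrow(pos) >= 4) {
    fit <- tryCatch(
      fit_logistic(curve_series(pos$round, pos$variant_count,
                                log_base = config$log_base),
                   orientation = "falling"),
      error = function(e) {
        warning("saturation fit failed: ", conditionMessage(e))
        NULL
      })
  } else {
    warning("too few rounds with nonzero variant counts for a saturation fit; ",
            "optimal round count unavailable")
  }
  if (!is.null(fit)) {
    optimal_n <- tryCatch(optimal_iterations(fit, config$tau),
                          error = function(e) {
                            warning(conditionMessage(e))
                            NA_integer_
                          })
  }
  final_round <- if (!is.na(optimal_n)) min(optimal_n, length(genomes) - 1L)
                 else length(genomes) - 1L
  structure(list(final = genomes[[final_round + 1L]], trace = trace, fit = fit,
                 optimal_n = optimal_n, final_round = final_round,
                 genomes = genomes, config = config),
            class = "iterref_result")
}

#' @export
print.iterref_result <- function(x, ...) {
  cat("<iterref_result> ", nrow(x$trace), " round(s); optimal round = ",
      x$optimal_n, "; final genome from round ", x$final_round, "\n", sep = "")
  print(x$trace, n = 8)
  invisible(x)
}

#' @export
tidy.iterref_result <- function(x, ...) tibble::as_tibble(x$trace)

#' @export
glance.iterref_result <- function(x, ...) {
  tibble::tibble(
    n_rounds = nrow(x$trace),
    optimal_n = x$optimal_n,
    total_substitutions = sum(x$trace$n_substitutions),
    final_mapping_rate = x$trace$mapping_rate[nrow(x$trace)],
    fit_r_squared = if (is.null(x$fit)) NA_real_ else x$fit$r_squared
  )
}

#' Plot per-round metrics of an iteration trace
#'
#' @param object An `iterref_trace` (or `iterref_result`).
#' @param ... Ignored.
#' @return A ggplot of log2 variant counts and mapping rate by round.
#' @export
autoplot.iterref_trace <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d_long <- tidyr::pivot_longer(
    dplyr::transmute(d, round = .data$round,
                     `log2 variant count` = log2(pmax(.data$variant_count, 1)),
                     `mapping rate` = .data$mapping_rate),
    -"round", names_to = "metric", values_to = "value")
  ggplot2::ggplot(d_long, ggplot2::aes(x = .data$round, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration round", y = NULL)
}

#' @export
autoplot.iterref_result <- function(object, ...) autoplot.iterref_trace(object$trace, ...)

#' Coverage titration: variant saturation against sequencing depth
#'
#' Downsamples a read pool to each requested coverage, maps, calls, and
#' records variant count, mapping rate, coverage ratio and sensitivity
#' against a gold-standard callset (by default the callset at the deepest
#' requested coverage, standing in for an excessive-coverage callset).
#'
#' @param reference The reference [genome].
#' @param read_pool Read tibble at (at least) the maximum coverage.
#' @param coverages Coverages to titrate (default `1:30`).
#' @param mapper,caller Parameter lists.
#' @param gold_coverage Coverage whose callset is the gold standard.
#' @param seed Seed for the random downsampling.
#' @return An `iterref_titration` tibble: `coverage, variant_count,
#'   mapping_rate, coverage_ratio, sensitivity`.
#' @export
run_coverage_titration <- function(reference, read_pool, coverages = 1:30,
                                   mapper = mapper_params(),
                                   caller = caller_params(),
                                   gold_coverage = max(coverages),
                                   seed = NULL) {
  reference <- as_genome(reference)
  G <- sum(genome_lengths(reference))
  L <- nchar(read_pool$seq[1])
  idx <- build_index(reference, mapper$k)
  call_at <- function(cov, step) {
    sub <- downsample_reads(read_pool, cov, G, L, seed = child_seed(seed, step))
    aln <- map_reads(sub, idx, mapper)
    list(aln = aln, calls = pileup_and_call(aln, reference, caller))
  }
  gold <- call_at(gold_coverage, 0L)$calls
  rows <- purrr::imap(coverages, function(cov, i) {
    res <- call_at(cov, i)
    cmp <- compare_callsets(res$calls, gold)
    tibble::tibble(coverage = cov,
                   variant_count = nrow(res$calls),
                   mapping_rate = mapping_rate(res$aln),
                   coverage_ratio = coverage_ratio(res$aln, reference),
                   sensitivity = cmp$sensitivity)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "gold") <- gold
  attr(out, "gold_coverage") <- gold_coverage
  class(out) <- c("iterref_titration", class(out))
  out
}

#' Plot a coverage titration
#'
#' @param object An `iterref_titration`.
#' @param ... Ignored.
#' @return A ggplot of log2 variant count against coverage.
#' @export
autoplot.iterref_titration <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$coverage,
                                  y = log2(pmax(.data$variant_count, 1)))) +
    ggplot2::geom_point(colour = "darkgreen") + ggplot2::geom_line() +
    ggplot2::labs(x = "coverage (x)", y = "log2 variant count")
}
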
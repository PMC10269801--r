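#' Normalize functional read counts within each taxon and sample
#'
#' Converts a long-format transcript count table into relative abundances
#' by dividing each functional category's reads by the total reads
#' assigned to that taxon in that sample. This is the normalization behind
#' taxon-resolved transcript-budget comparisons: the proportion of a
#' taxon's transcriptional output devoted to a function, independent of
#' how abundant the taxon itself is in the sample.
#'
#' (sample, taxon) groups whose total read count is zero cannot be
#' normalized and are dropped with a warning.
#'
#' @param counts a data frame with columns `sample`, `taxon`, `function_`
#'   (functional category; named with a trailing underscore because
#'   `function` is reserved in R), `read_count`, and optionally
#'   `size_fraction`. (`sample`, `taxon`, `function_`) must be unique.
#' @return a tibble with the same keys and a `proportion` column; within
#'   each (sample, taxon) the proportions sum to 1.
#' @export
#' @examples
#' tt <- synthesize_metatranscriptome(n_samples = 4, seed = 1)
#' ra <- normalize_transcripts(tt)
#' dplyr::count(ra, sample, taxon, wt = proportion)  # all 1
normalize_transcripts <- function(counts) {
  needed <- c("sample", "taxon", "function_", "read_count")
  if (!all(needed %in% names(counts))) {
    stop("count table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts$read_count < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(counts[, c("sample", "taxon", "function_")])) {
    stop("(sample, taxon, function_) rows must be unique", call. = FALSE)
  }
  ra <- counts |>
    dplyr::group_by(.data$sample, .data$taxon) |>
    dplyr::mutate(taxon_total = sum(.data$read_count)) |>
    dplyr::ungroup()
  empty <- ra$taxon_total == 0
  if (any(empty)) {
    dropped <- unique(ra[empty, c("sample", "taxon")])
    warning(nrow(dropped), " (sample, taxon) group(s) with zero total ",
            "reads dropped", call. = FALSE)
    ra <- ra[!empty, ]
  }
  ra$proportion <- ra$read_count / ra$taxon_total
  ra$taxon_total <- NULL
  ra$read_count <- NULL
  tibble::as_tibble(ra)
}

#' Paired comparison of a function's relative abundance between two taxa
#'
#' For one functional category, pairs the relative abundances of two taxa
#' within each sample where both are present — the per-point comparison of
#' a scatterplot against the 1:1 diagonal — and summarizes the pairs: how
#' many lie above the diagonal (taxon A greater), how many are ties, and
#' the median log2 ratio A/B. Pairs with a zero proportion on either side
#' are excluded from the log ratio and tallied separately; no pseudocount
#' is added.
#'
#' @param ra a relative-abundance tibble from [normalize_transcripts()].
#' @param fun functional category to compare.
#' @param taxon_a,taxon_b the two taxa.
#' @return an object of class `paired_comparison`: a list with the
#'   per-sample `pairs` tibble and the summary fields `n_pairs`,
#'   `n_above` (A > B), `n_ties`, `frac_above`, `n_zero_excluded`, and
#'   `median_log2_ratio`.
#' @export
#' @examples
#' tt <- synthesize_metatranscriptome(n_samples = 20, seed = 11)
#' ra <- normalize_transcripts(tt)
#' paired_comparison(ra, "ribosomal_protein",
#'                   "diatom", "other_photosynthetic_protist")
paired_comparison <- function(ra, fun, taxon_a, taxon_b) {
  sub <- ra[ra$function_ == fun, ]
  a <- sub[sub$taxon == taxon_a, c("sample", "proportion")]
  b <- sub[sub$taxon == taxon_b, c("sample", "proportion")]
  pairs <- dplyr::inner_join(a, b, by = "sample",
                             suffix = c("_a", "_b"))
  if (nrow(pairs) == 0) {
    stop("taxa '", taxon_a, "' and '", taxon_b,
         "' share no samples for function '", fun, "'", call. = FALSE)
  }
  nonzero <- pairs$proportion_a > 0 & pairs$proportion_b > 0
  log2_ratio <- log2(pairs$proportion_a[nonzero] /
                       pairs$proportion_b[nonzero])
  structure(
    list(
      function_ = fun, taxon_a = taxon_a, taxon_b = taxon_b,
      pairs = tibble::as_tibble(pairs),
      n_pairs = nrow(pairs),
      n_above = sum(pairs$proportion_a > pairs$proportion_b),
      n_ties = sum(pairs$proportion_a == pairs$proportion_b),
      frac_above = mean(pairs$proportion_a > pairs$proportion_b),
      n_zero_excluded = sum(!nonzero),
      median_log2_ratio = if (length(log2_ratio)) median(log2_ratio)
                          else NA_real_
    ),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("<paired_comparison>", x$function_, ":", x$taxon_a, "vs", x$taxon_b,
      "\n")
  cat(sprintf("  %d sample pairs; %d above the 1:1 line (%.1f%%), %d ties\n",
              x$n_pairs, x$n_above, 100 * x$frac_above, x$n_ties))
  cat(sprintf("  median log2 ratio: %.3f (%d zero pair(s) excluded)\n",
              x$median_log2_ratio, x$n_zero_excluded))
  cat("  (summary statistics are descriptive additions; the underlying\n",
      "  comparison is the per-sample scatter against the 1:1 line)\n")
  invisible(x)
}

#' Generate a synthetic taxon-by-function metatranscriptome count table
#'
#' Emulates the shape of a size-fractionated ocean metatranscriptome
#' survey summarized to taxon-by-function read counts. For every
#' (sample, taxon) the total read count is lognormal and the counts over
#' functional categories are multinomial around taxon-specific base
#' proportions. Diatoms receive a multiplicative uplift on
#' `ribosomal_protein` and a reduction on the cytoskeleton categories
#' (`actin`, `tubulin`) relative to the other taxa; the residual `other`
#' category absorbs the complement so proportions stay on the simplex.
#' Fully reproducible for a given seed.
#'
#' @param n_samples number of samples (stations).
#' @param config a configuration list; the `transcripts` block supplies
#'   total-read lognormal parameters, base proportions, and the diatom
#'   effects.
#' @param taxa taxon labels; the first is treated as the diatom group.
#' @param seed integer seed.
#' @return a tibble with columns `sample`, `size_fraction`, `taxon`,
#'   `function_`, `read_count`, one row per combination.
#' @export
synthesize_metatranscriptome <- function(n_samples = 66,
                                         config = default_config(),
                                         taxa = c("diatom",
                                                  "other_photosynthetic_protist"),
                                         seed = 1) {
  stopifnot(n_samples >= 1)
  tc <- config$transcripts
  base <- unlist(tc$base_proportions)
  props <- list()
  for (taxon in taxa) {
    p <- base
    if (taxon == taxa[[1]]) {  # the diatom group carries the effects
      p[["ribosomal_protein"]] <- p[["ribosomal_protein"]] * tc$ribosomal_uplift
      p[["actin"]] <- p[["actin"]] * tc$cytoskeleton_factor
      p[["tubulin"]] <- p[["tubulin"]] * tc$cytoskeleton_factor
    }
    p[["other"]] <- 1 - sum(p[names(p) != "other"])
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("adjusted proportions for taxon '", taxon,
           "' are not a valid probability vector", call. = FALSE)
    }
    props[[taxon]] <- p
  }
  set.seed(derive_seed(seed, "metatranscriptome"))
  fractions <- c("0.8-5um", "5-20um", "20-180um", "180-2000um")
  funs <- names(base)
  n_fun <- length(funs)
  n_groups <- n_samples * length(taxa)
  counts <- integer(n_groups * n_fun)
  sample_id <- character(n_groups)
  taxon_id <- character(n_groups)
  k <- 0
  for (s in seq_len(n_samples)) {
    for (taxon in taxa) {
      total <- round(rlnorm(1, tc$total_meanlog, tc$total_sdlog))
      k <- k + 1
      counts[((k - 1) * n_fun + 1):(k * n_fun)] <-
        rmultinom(1, total, props[[taxon]])
      sample_id[k] <- sprintf("S%03d", s)
      taxon_id[k] <- taxon
    }
  }
  sample_rep <- rep(sample_id, each = n_fun)
  idx <- as.integer(sub("S", "", sample_rep))
  tibble::tibble(
    sample = sample_rep,
    size_fraction = fractions[(idx - 1) %% length(fractions) + 1],
    taxon = rep(taxon_id, each = n_fun),
    function_ = rep(funs, times = n_groups),
    read_count = counts
  )
}
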
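#' Low-count gene pre-filter
#'
#' Mirrors the standard pre-filter applied before differential
#' expression testing: a gene is kept only if its counts-per-million
#' strictly exceed `cpm_threshold` in at least `min_samples` samples.
#'
#' @param counts A [count_table()] object or count matrix.
#' @param cpm_threshold CPM cutoff, exceeded strictly (default 1).
#' @param min_samples Minimum number of samples above the cutoff
#'   (default 3).
#' @return Character vector of retained gene ids.
#' @export
filter_low_counts <- function(counts, cpm_threshold = 1, min_samples = 3) {
  if (inherits(counts, "count_table")) {
    C <- counts$counts; N <- counts$library_sizes
  } else {
    C <- as.matrix(counts); N <- colSums(C)
  }
  cpm <- sweep(C, 2, N / 1e6, "/")
  rownames(C)[rowSums(cpm > cpm_threshold) >= min_samples]
}

#' Read a differential-expression result table
#'
#' Expects TSV columns `gene`, `mean_sorted`, `mean_unsorted_head`,
#' `mean_unsorted_trunk`, `fdr` (the multiple-testing-adjusted
#' significance from whichever DE engine produced the table).
#'
#' @param path TSV file path.
#' @return data.frame with the five required columns.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  validate_de_table(df)
}

validate_de_table <- function(df) {
  need <- c("gene", "mean_sorted", "mean_unsorted_head",
            "mean_unsorted_trunk", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DE table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(df$mean_sorted) | is.na(df$mean_unsorted_head) |
          is.na(df$mean_unsorted_trunk)))
    stop("DE table contains missing group means")
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE))
    stop("fdr values must lie in [0, 1]")
  df
}

#' Call genes enriched in a sorted cell population
#'
#' A gene is enriched when (i) it is significant at `fdr_threshold`
#' (inclusive) and (ii) its mean expression in the sorted population
#' exceeds both unsorted backgrounds (head and trunk).
#'
#' @param results data.frame as returned by [read_de_table()].
#' @param fdr_threshold FDR cutoff, inclusive (default 0.05).
#' @return Character vector of enriched gene ids.
#' @export
call_enriched <- function(results, fdr_threshold = 0.05) {
  results <- validate_de_table(results)
  keep <- results$fdr <= fdr_threshold &
    results$mean_sorted > results$mean_unsorted_head &
    results$mean_sorted > results$mean_unsorted_trunk
  as.character(results$gene[keep & !is.na(keep)])
}

#' Partition two enriched gene sets into specific and common signatures
#'
#' @param ep_enriched,tre_enriched Character vectors of enriched gene
#'   ids for the two populations (eye photoreceptor and trunk
#'   r-opsin-expressing cells, in the motivating application).
#' @return Object of class `signature_sets`: list with `ep_enriched`,
#'   `tre_enriched`, `common` (intersection), `ep_specific`,
#'   `tre_specific` (set differences).
#' @export
partition_signatures <- function(ep_enriched, tre_enriched) {
  ep <- unique(as.character(ep_enriched))
  tre <- unique(as.character(tre_enriched))
  structure(list(
    ep_enriched = ep,
    tre_enriched = tre,
    common = intersect(ep, tre),
    ep_specific = setdiff(ep, tre),
    tre_specific = setdiff(tre, ep)
  ), class = "signature_sets")
}

#' @export
print.signature_sets <- function(x, ...) {
  cat("Signature sets:\n",
      "  EP-enriched:  ", length(x$ep_enriched), "\n",
      "  TRE-enriched: ", length(x$tre_enriched), "\n",
      "  common:       ", length(x$common), "\n",
      "  EP-specific:  ", length(x$ep_specific), "\n",
      "  TRE-specific: ", length(x$tre_specific), "\n", sep = "")
  invisible(x)
}

#' Signature sizes as percentages of a gene universe
#'
#' @param sets A `signature_sets` object.
#' @param universe_size Total number of genes tested.
#' @param digits Rounding for the percentages (default 1).
#' @return Named numeric vector of percentages.
#' @export
signature_percentages <- function(sets, universe_size, digits = 1) {
  n <- c(ep_enriched = length(sets$ep_enriched),
         tre_enriched = length(sets$tre_enriched),
         common = length(sets$common),
         ep_specific = length(sets$ep_specific),
         tre_specific = length(sets$tre_specific))
  round(100 * n / universe_size, digits)
}

#' Expression-based specificity triple
#'
#' Splits two expressed-gene sets into population-specific and shared
#' portions: a gene is specifically expressed in one population when it
#' is expressed there and not in the other.
#'
#' @param ep_expressed,tre_expressed Character vectors of expressed
#'   gene ids.
#' @return List with `ep_only`, `both`, `tre_only`.
#' @export
expressed_specific <- function(ep_expressed, tre_expressed) {
  ep <- unique(as.character(ep_expressed))
  tre <- unique(as.character(tre_expressed))
  list(ep_only = setdiff(ep, tre),
       both = intersect(ep, tre),
       tre_only = setdiff(tre, ep))
}
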
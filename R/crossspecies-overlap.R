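#' Read tabular homology hits (BLAST outfmt-6 layout)
#'
#' Reads a tab-separated hit table in the standard 12-column tabular
#' BLAST layout (qseqid, sseqid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore), with or without a
#' header. Only the query id, subject id, e-value and bit-score columns
#' are consumed.
#'
#' @param path TSV file path.
#' @return data.frame with columns `query_gene`, `target_gene`,
#'   `e_value`, `bit_score`.
#' @export
read_blast_hits <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("qseqid|query", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (has_header) {
    nm <- tolower(names(df))
    qi <- match(TRUE, nm %in% c("qseqid", "query_gene", "query"))
    si <- match(TRUE, nm %in% c("sseqid", "target_gene", "subject"))
    ei <- match(TRUE, nm %in% c("evalue", "e_value"))
    bi <- match(TRUE, nm %in% c("bitscore", "bit_score"))
    if (any(is.na(c(qi, si, ei)))) stop("unrecognized hit-table header")
    out <- data.frame(query_gene = as.character(df[[qi]]),
                      target_gene = as.character(df[[si]]),
                      e_value = as.numeric(df[[ei]]),
                      bit_score = if (!is.na(bi)) as.numeric(df[[bi]]) else NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(df) < 12) stop("headerless hit table must have 12 columns")
    out <- data.frame(query_gene = as.character(df[[1]]),
                      target_gene = as.character(df[[2]]),
                      e_value = as.numeric(df[[11]]),
                      bit_score = as.numeric(df[[12]]),
                      stringsAsFactors = FALSE)
  }
  bad <- which(is.na(out$query_gene) | is.na(out$target_gene) |
                 is.na(out$e_value) | out$e_value <= 0)
  if (length(bad))
    stop("malformed hit row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  out
}

#' Best-hit homology map
#'
#' Assigns each query-species gene its single best target-species hit:
#' the hit with the lowest e-value at or below `e_threshold`, ties
#' broken by higher bit-score, then lexicographic target id. Queries
#' with no qualifying hit are absent from the map. Many queries may
#' share one target.
#'
#' @param hits data.frame as from [read_blast_hits()] (columns
#'   `query_gene`, `target_gene`, `e_value`, optional `bit_score`).
#' @param e_threshold Maximum e-value (default `1e-20`; relax to
#'   `1e-8` for divergent short proteins when the stringent cutoff
#'   yields no hit).
#' @return Named character vector: `map[query] == target`.
#' @export
best_hit_map <- function(hits, e_threshold = 1e-20) {
  need <- c("query_gene", "target_gene", "e_value")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hits lack column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(hits$query_gene) | is.na(hits$target_gene) |
                 is.na(hits$e_value) | hits$e_value <= 0)
  if (length(bad))
    stop("malformed hit row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  h <- hits[hits$e_value <= e_threshold, , drop = FALSE]
  if (!nrow(h)) return(stats::setNames(character(0), character(0)))
  bs <- if ("bit_score" %in% names(h)) h$bit_score else rep(0, nrow(h))
  bs[is.na(bs)] <- -Inf
  ord <- order(h$query_gene, h$e_value, -bs, h$target_gene)
  h <- h[ord, , drop = FALSE]
  first <- !duplicated(h$query_gene)
  stats::setNames(h$target_gene[first], h$query_gene[first])
}

#' Observed cross-species overlap
#'
#' Number of distinct target-species genes that (i) are the mapped
#' homolog of at least one gene in the query set and (ii) belong to the
#' target signature.
#'
#' @param query_set Character vector of query-species gene ids.
#' @param map Named character vector from [best_hit_map()].
#' @param signature Character vector of target-species gene ids.
#' @return Nonnegative integer count.
#' @export
observed_overlap <- function(query_set, map, signature) {
  targets <- unique(map[intersect(unique(query_set), names(map))])
  length(intersect(targets, signature))
}

#' Permutation test for cross-species gene-set overlap
#'
#' Tests whether the homologs of a query gene set overlap a target
#' signature more than expected for a random query set of the same
#' size. The null is built by drawing `n_perm` sets of `set_size` genes
#' uniformly without replacement from the query-species universe and
#' recomputing the same distinct-target overlap statistic. The p-value
#' is the fraction of null sets with overlap greater than or equal to
#' the observed one; when no null set reaches it, the p-value is
#' reported as the resolution bound `1/n_perm` with `p_is_bound = TRUE`
#' (read "p < 1/n_perm").
#'
#' @param universe Character vector: all query-species gene ids random
#'   sets are drawn from.
#' @param query_set Character vector, the real gene set (drawn from
#'   `universe`).
#' @param map Named character vector from [best_hit_map()].
#' @param signature Character vector of target signature gene ids.
#' @param set_size Size of the permuted sets (default `length(query_set)`).
#' @param n_perm Number of random sets (default 10000).
#' @param seed Integer seed for reproducibility (default 1).
#' @return Object of class `overlap_result`: list with `observed`,
#'   `n_perm`, `n_geq`, `p_value`, `p_is_bound`, `seed`, `null_mean`,
#'   `null_sd`, `null_overlaps`.
#' @export
permutation_overlap_test <- function(universe, query_set, map, signature,
                                     set_size = length(unique(query_set)),
                                     n_perm = 10000, seed = 1) {
  universe <- unique(as.character(universe))
  if (set_size > length(universe))
    stop("set_size (", set_size, ") exceeds universe size (",
         length(universe), ")")
  stopifnot(n_perm >= 1)
  obs <- observed_overlap(query_set, map, signature)

  # integer encoding: target index per universe gene (NA = unmapped),
  # plus signature membership per target index
  tgt_all <- unique(map)
  tgt_idx <- match(map[universe], tgt_all)    # NA for unmapped queries
  in_sig <- tgt_all %in% signature

  null_overlaps <- integer(n_perm)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  nu <- length(universe)
  for (b in seq_len(n_perm)) {
    idx <- tgt_idx[sample.int(nu, set_size)]
    null_overlaps[b] <- sum(in_sig[unique(idx[!is.na(idx)])])
  }
  n_geq <- sum(null_overlaps >= obs)
  structure(list(
    observed = obs,
    n_perm = n_perm,
    n_geq = n_geq,
    p_value = if (n_geq > 0) n_geq / n_perm else 1 / n_perm,
    p_is_bound = n_geq == 0,
    seed = seed,
    null_mean = mean(null_overlaps),
    null_sd = stats::sd(null_overlaps),
    null_overlaps = null_overlaps
  ), class = "overlap_result")
}

#' Randomized (exactly uniform) p-value for calibration diagnostics
#'
#' The plain permutation p-value of an integer-valued overlap statistic
#' is discrete: it only attains the survival values of the null
#' distribution, so its null distribution is sub-uniform and a naive
#' uniformity check (e.g. Kolmogorov-Smirnov against U(0,1)) rejects
#' even when the test is perfectly calibrated. The standard randomized
#' construction `(#{null > obs} + U * (1 + #{null = obs})) /
#' (n_perm + 1)` with `U ~ U(0,1)` is exactly uniform under the null
#' and is what calibration studies should use. For reporting
#' significance, use the plain `p_value` of the result.
#'
#' @param result An `overlap_result` from [permutation_overlap_test()].
#' @param u Optional uniform draw in (0, 1); defaults to `runif(1)`.
#' @return A single randomized p-value in (0, 1).
#' @export
randomized_p <- function(result, u = stats::runif(1)) {
  stopifnot(inherits(result, "overlap_result"))
  n_gt <- sum(result$null_overlaps > result$observed)
  n_eq <- sum(result$null_overlaps == result$observed)
  (n_gt + u * (1 + n_eq)) / (result$n_perm + 1)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Cross-species overlap permutation test\n",
      "  observed overlap: ", x$observed, " distinct target genes\n",
      "  null (", x$n_perm, " sets): mean ", signif(x$null_mean, 3),
      ", sd ", signif(x$null_sd, 3), "\n",
      "  p ", if (x$p_is_bound) "< " else "= ", signif(x$p_value, 3),
      "\n", sep = "")
  invisible(x)
}

# Save/restore .Random.seed so a seeded test does not perturb the
# caller's RNG stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
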
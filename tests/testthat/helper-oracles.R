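# Independent oracles used to cross-check the implementation.

rc <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]),
        collapse = "")
}

substr_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

# Brute-force clustering oracle: all-pairs shared-substring check
# (forward and reverse-complement), transitive closure via igraph
# connected components. Returns a partition as a list of sorted id
# vectors.
oracle_cluster <- function(transcripts, k = 50) {
  ids <- names(transcripts)
  n <- length(transcripts)
  sets_f <- lapply(transcripts, substr_set, k = k)
  sets_r <- lapply(transcripts, function(s) substr_set(rc(s), k))
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (length(intersect(sets_f[[i]], sets_f[[j]])) ||
        length(intersect(sets_f[[i]], sets_r[[j]])))
      edges <- rbind(edges, c(i, j))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  unname(lapply(split(ids, comp), sort))
}

as_partition <- function(clusters) {
  unname(lapply(clusters, function(cl) sort(cl$member_ids)))
}

expect_same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, paste, character(1), collapse = "|"))
  expect_identical(key(a), key(b))
}

# Interval-union oracle for nominal lengths: members are intervals of a
# master sequence; the unique-sequence length is the reduced-interval
# width sum (IRanges).
oracle_union_length <- function(starts, widths) {
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = starts,
                                                      width = widths))))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Closed-form hypergeometric survival probability P(X >= k) for the
# permutation-null oracle.
hyper_tail <- function(k, n_success, n_total, n_draw) {
  stats::phyper(k - 1, n_success, n_total - n_success, n_draw,
                lower.tail = FALSE)
}

# Exhaustive grid-search 4PL oracle (bottom fixed), minimizing sse over
# a (top, hill, logEC50) grid.
oracle_4pl_grid <- function(x, y, baseline,
                            top_grid, hill_grid, le_grid) {
  best <- list(sse = Inf)
  for (T in top_grid) for (h in hill_grid) {
    # vectorize over logEC50
    for (e in le_grid) {
      r <- baseline + (T - baseline) / (1 + 10^(h * (e - x)))
      sse <- sum((y - r)^2)
      if (sse < best$sse) best <- list(top = T, hill = h,
                                       log_ec50 = e, sse = sse)
    }
  }
  best
}

# Independent fine-grid template scan (0.1 nm), written as a plain loop
# against the same closed-form template.
oracle_lambda_scan <- function(wavelength, sensitivity,
                               lo = 400, hi = 550, step = 0.1) {
  grid <- seq(lo, hi, by = step)
  best <- grid[1]; best_ss <- Inf
  for (lm in grid) {
    ss <- sum((sensitivity - govardovskii_template(wavelength, lm))^2)
    if (ss < best_ss) { best_ss <- ss; best <- lm }
  }
  best
}

# Deterministic sinusoidal window for classifier tests.
sine_window <- function(freq, amp, fps = 10, window_s = 10,
                        point = "body3", base_y = 50) {
  n <- round(window_s * fps)
  t <- (seq_len(n) - 1) / fps
  x <- matrix(rep(20 * (1:5), each = n), n, 5,
              dimnames = list(NULL, paste0("body", 1:5)))
  y <- matrix(base_y, n, 5, dimnames = list(NULL, paste0("body", 1:5)))
  y[, point] <- base_y + amp * sin(2 * pi * freq * t)
  list(x = x, y = y, fps = fps)
}
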
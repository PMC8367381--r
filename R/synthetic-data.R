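#' @title Seed-deterministic synthetic data with ground truth
#' @name synthetic-data
#' @description
#' Generators that emulate every input class the pipeline consumes —
#' overlapping transcript clusters, negative-binomial count experiments
#' with planted enriched genes, many-to-one homology universes with
#' planted signature enrichment, dose-response curves generated from a
#' pigment template at known peak wavelength, and keypoint tracks with
#' scheduled sinusoidal undulation bouts. Each generator returns its
#' ground truth alongside the data and is bit-identical for identical
#' arguments and seed.
NULL

with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate transcript clusters with planted exact overlaps
#'
#' Each cluster is a chain of transcripts in which consecutive members
#' share an exact `overlap_len`-bp substring (the suffix of one is the
#' prefix of the next); transcripts of different clusters are
#' rejection-checked to share no 50-mer on either strand.
#'
#' @param n_clusters Number of clusters.
#' @param members_per_cluster Transcripts per cluster.
#' @param member_len Length of each transcript in bp.
#' @param overlap_len Planted overlap length in bp (>= 50, <
#'   `member_len`).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempts per cluster before
#'   giving up.
#' @return List with `transcripts` (named character vector),
#'   `truth` (data.frame `id`, `cluster`), and `nominal_lengths`
#'   (named by cluster: `member_len + (m - 1) * (member_len -
#'   overlap_len)`).
#' @export
gen_transcript_clusters <- function(n_clusters, members_per_cluster,
                                    member_len = 300, overlap_len = 60,
                                    seed = 1, max_tries = 100) {
  stopifnot(overlap_len < member_len, overlap_len >= 50)
  with_seed(seed, {
    seen_kmers <- character(0)
    transcripts <- character(0)
    truth <- list()
    for (cl in seq_len(n_clusters)) {
      for (try in seq_len(max_tries)) {
        members <- character(members_per_cluster)
        members[1] <- random_dna(member_len)
        if (members_per_cluster > 1) {
          for (m in 2:members_per_cluster) {
            ov <- substr(members[m - 1], member_len - overlap_len + 1,
                         member_len)
            members[m] <- paste0(ov, random_dna(member_len - overlap_len))
          }
        }
        km <- unique(canonical_kmers(
          unlist(lapply(members, seq_kmers, k = 50), use.names = FALSE)))
        if (!any(km %in% seen_kmers)) break
        if (try == max_tries)
          stop("could not generate cluster ", cl,
               " without cross-cluster 50-mer sharing")
      }
      seen_kmers <- c(seen_kmers, km)
      ids <- sprintf("cl%d_t%d", cl, seq_len(members_per_cluster))
      names(members) <- ids
      transcripts <- c(transcripts, members)
      truth[[cl]] <- data.frame(id = ids, cluster = paste0("cl", cl))
    }
    list(transcripts = transcripts,
         truth = do.call(rbind, truth),
         nominal_lengths = stats::setNames(
           rep(member_len + (members_per_cluster - 1) *
                 (member_len - overlap_len), n_clusters),
           paste0("cl", seq_len(n_clusters))))
  })
}

#' Simulate a negative-binomial count experiment with planted
#' enrichment
#'
#' Three groups (sorted, unsorted_head, unsorted_trunk) with
#' `n_reps` replicates each. A fraction of genes is planted as enriched
#' in the sorted group at `fold_change` times the background
#' abundance; counts are negative-binomial around
#' composition-scaled library sizes. The emitted
#' differential-expression table carries group CPM means and FDRs
#' consistent with the truth (planted genes below 0.05, others above),
#' with an optional label-flip error rate.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per group (default 3).
#' @param frac_enriched Fraction of planted enriched genes.
#' @param fold_change Sorted-group fold change for planted genes (> 1).
#' @param nb_dispersion Negative-binomial dispersion (default 0.1, a
#'   typical bulk-RNA-seq biological coefficient of variation squared).
#' @param library_size Expected reads per sample (default 1e6).
#' @param error_rate Fraction of genes whose FDR label is flipped
#'   (default 0).
#' @param seed Integer seed.
#' @return List with `counts` (a [count_table()]), `de` (data.frame
#'   `gene`, `mean_sorted`, `mean_unsorted_head`, `mean_unsorted_trunk`,
#'   `fdr`), and `truth_enriched` (character vector).
#' @export
gen_count_experiment <- function(n_genes, n_reps = 3, frac_enriched = 0.05,
                                 fold_change = 20, nb_dispersion = 0.1,
                                 library_size = 1e6, error_rate = 0,
                                 seed = 1) {
  stopifnot(frac_enriched >= 0, frac_enriched <= 1, fold_change > 1)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    n_enriched <- round(frac_enriched * n_genes)
    enriched <- if (n_enriched) sample(genes, n_enriched) else character(0)
    base <- stats::rgamma(n_genes, shape = 2, scale = 25) + 5
    names(base) <- genes
    rel_sorted <- base
    rel_sorted[enriched] <- base[enriched] * fold_change
    groups <- c("sorted", "unsorted_head", "unsorted_trunk")
    samples <- paste(rep(groups, each = n_reps), seq_len(n_reps), sep = "_")
    C <- matrix(0L, n_genes, length(samples),
                dimnames = list(genes, samples))
    for (s in seq_along(samples)) {
      rel <- if (startsWith(samples[s], "sorted")) rel_sorted else base
      mu <- rel / sum(rel) * library_size
      C[, s] <- stats::rnbinom(n_genes, mu = mu, size = 1 / nb_dispersion)
    }
    ct <- count_table(C)
    cpm <- sweep(C, 2, ct$library_sizes / 1e6, "/")
    gmean <- function(g) rowMeans(cpm[, startsWith(samples, g), drop = FALSE])
    is_enr <- genes %in% enriched
    flip <- stats::runif(n_genes) < error_rate
    below <- xor(is_enr, flip)
    fdr <- ifelse(below, stats::runif(n_genes, 0, 0.049),
                  stats::runif(n_genes, 0.051, 1))
    de <- data.frame(gene = genes,
                     mean_sorted = gmean("sorted"),
                     mean_unsorted_head = gmean("unsorted_head"),
                     mean_unsorted_trunk = gmean("unsorted_trunk"),
                     fdr = fdr, row.names = NULL)
    list(counts = ct, de = de, truth_enriched = sort(enriched))
  })
}

#' Simulate a homology universe with a planted signature overlap
#'
#' Builds a query-species gene universe, a best-hit map onto a target
#' species (injective or many-to-one), a target signature, and a query
#' gene set whose mapped homologs hit the signature at
#' `planted_enrichment` times the background rate. Strong hits carry
#' e-values below 1e-20; weak decoy hits above the threshold are added
#' for realism.
#'
#' @param n_query,n_target Universe sizes.
#' @param mapped_frac Fraction of queries with a qualifying hit.
#' @param injective Force distinct targets per mapped query.
#' @param signature_size Number of signature targets.
#' @param planted_enrichment Signature hit-rate multiplier for the
#'   query set (>= 1; 1 = null, set drawn uniformly).
#' @param query_set_size Size of the real query set.
#' @param seed Integer seed.
#' @return List with `hits` (data.frame `query_gene`, `target_gene`,
#'   `e_value`, `bit_score`), `universe`, `query_set`, `signature`,
#'   and `truth_overlap` (distinct mapped signature targets of the
#'   query set).
#' @export
gen_homology_universe <- function(n_query = 1000, n_target = 800,
                                  mapped_frac = 0.6, injective = FALSE,
                                  signature_size = 100,
                                  planted_enrichment = 1,
                                  query_set_size = 50, seed = 1) {
  stopifnot(signature_size <= n_target, planted_enrichment >= 1,
            query_set_size <= n_query)
  with_seed(seed, {
    universe <- sprintf("q%05d", seq_len(n_query))
    targets <- sprintf("t%05d", seq_len(n_target))
    n_mapped <- round(mapped_frac * n_query)
    if (injective && n_mapped > n_target)
      stop("injective map impossible: more mapped queries than targets")
    mapped_q <- sample(universe, n_mapped)
    mapped_t <- if (injective) sample(targets, n_mapped)
                else sample(targets, n_mapped, replace = TRUE)
    map <- stats::setNames(mapped_t, mapped_q)
    signature <- sample(targets, signature_size)

    in_sig <- universe %in% mapped_q & map[universe] %in% signature
    if (planted_enrichment == 1) {
      query_set <- sample(universe, query_set_size)
    } else {
      p0 <- mean(in_sig)
      k <- round(query_set_size * min(1, planted_enrichment * p0))
      pool_in <- universe[in_sig]
      pool_out <- universe[!in_sig]
      if (k > length(pool_in) || query_set_size - k > length(pool_out))
        stop("infeasible planted enrichment for the given sizes")
      query_set <- c(sample(pool_in, k),
                     sample(pool_out, query_set_size - k))
    }

    hits <- data.frame(
      query_gene = mapped_q, target_gene = unname(mapped_t),
      e_value = 10^-stats::runif(n_mapped, 21, 80),
      bit_score = round(stats::runif(n_mapped, 100, 500), 1))
    n_decoy <- round(0.2 * n_query)
    if (n_decoy) {
      dq <- sample(universe, n_decoy)
      hits <- rbind(hits, data.frame(
        query_gene = dq,
        target_gene = sample(targets, n_decoy, replace = TRUE),
        e_value = 10^-stats::runif(n_decoy, 1, 15),
        bit_score = round(stats::runif(n_decoy, 20, 60), 1)))
    }
    hits <- hits[order(hits$query_gene, hits$e_value), ]
    rownames(hits) <- NULL
    list(hits = hits, universe = universe, query_set = sort(query_set),
         signature = signature,
         truth_overlap = observed_overlap(query_set, map, signature))
  })
}

#' Simulate per-wavelength dose-response data from a pigment template
#'
#' EC50s follow the pigment template: `EC50(lambda) = EC50_peak /
#' template(lambda, lambda_max)`, i.e. less absorbed wavelengths need
#' proportionally more photons. Responses are drawn from the 4PL curve
#' at `n_doses` log-spaced irradiances centred on each wavelength's
#' true logEC50, plus Gaussian noise. The default dose design mirrors
#' a neutral-density filter wheel spanning 3.5 optical densities in
#' 0.5 steps: 8 doses over 3.5 decades.
#'
#' @param lambda_max True peak wavelength (nm, within \[400, 550\]).
#' @param wavelengths Assay wavelengths in nm (default the nine
#'   bandpass filters 420, 442, 458, 480, 500, 520, 540, 568, 600).
#' @param hill Hill slope (default 1).
#' @param log_ec50_at_peak log10 EC50 at the peak wavelength (default
#'   13.5, photons cm-2 s-1).
#' @param top,baseline 4PL asymptotes in luminescence units (defaults
#'   500 and 100).
#' @param n_doses Doses per wavelength (default 8).
#' @param n_reps Independent replicate responses per dose (default 3,
#'   matching the assay's three independent replicates).
#' @param noise_sd Gaussian noise SD on responses (default 0).
#' @param seed Integer seed.
#' @return List with `doses` (data.frame `wavelength_nm`,
#'   `log_irradiance`, `replicate`, `response`) and `truth` (list with
#'   `lambda_max`, `log_ec50` per wavelength, `hill`, `top`,
#'   `baseline`).
#' @export
gen_action_spectrum_data <- function(lambda_max,
                                     wavelengths = c(420, 442, 458, 480,
                                                     500, 520, 540, 568,
                                                     600),
                                     hill = 1, log_ec50_at_peak = 13.5,
                                     top = 500, baseline = 100,
                                     n_doses = 8, n_reps = 3,
                                     noise_sd = 0, seed = 1) {
  stopifnot(lambda_max >= 400, lambda_max <= 550)
  with_seed(seed, {
    s <- govardovskii_template(wavelengths, lambda_max)
    log_ec50 <- log_ec50_at_peak - log10(s)
    rows <- lapply(seq_along(wavelengths), function(i) {
      x <- rep(seq(log_ec50[i] - 1.75, log_ec50[i] + 1.75,
                   length.out = n_doses), times = n_reps)
      r <- baseline + (top - baseline) /
        (1 + 10^(hill * (log_ec50[i] - x)))
      if (noise_sd > 0) r <- r + stats::rnorm(length(x), sd = noise_sd)
      data.frame(wavelength_nm = wavelengths[i], log_irradiance = x,
                 replicate = rep(seq_len(n_reps), each = n_doses),
                 response = r)
    })
    list(doses = do.call(rbind, rows),
         truth = list(lambda_max = lambda_max,
                      log_ec50 = stats::setNames(log_ec50, wavelengths),
                      hill = hill, top = top, baseline = baseline))
  })
}

#' Simulate keypoint tracks with scheduled undulation bouts
#'
#' Seven keypoints per animal; during scheduled bouts the five trunk
#' points oscillate sinusoidally in y with per-point phase offsets,
#' otherwise they sit still apart from optional slow linear drift.
#' Frames are dropped (per point) at `missing_rate`. The amplitude
#' parameter is the sine half-amplitude: peak-to-peak movement is
#' twice the scheduled amplitude.
#'
#' @param n_worms Number of animals.
#' @param fps Frames per second (default 5).
#' @param duration_s Recording duration in seconds.
#' @param bout_schedule data.frame with columns `start`, `end` (s),
#'   `freq` (Hz, below `fps/2`), `amp` (px half-amplitude); applied to
#'   every worm.
#' @param drift_px_per_s Linear drift speed (default 0).
#' @param missing_rate Per-point frame drop probability; scalar or
#'   named vector by keypoint (default 0).
#' @param genotype Group label (default `"wt"`).
#' @param t0 Recording start in hours (default 0).
#' @param worm_prefix Prefix for worm ids (default `"w"`).
#' @param seed Integer seed.
#' @return List with `tracks` (list of [keypoint_track()]) and
#'   `truth` (data.frame `worm_id`, `window_index`, `start_time`,
#'   `undulating`, `boundary`; `undulating` is `NA` for windows
#'   straddling a bout boundary).
#' @export
gen_tracks <- function(n_worms = 1, fps = 5, duration_s = 600,
                       bout_schedule = data.frame(start = numeric(0),
                                                  end = numeric(0),
                                                  freq = numeric(0),
                                                  amp = numeric(0)),
                       drift_px_per_s = 0, missing_rate = 0,
                       genotype = "wt", t0 = 0, worm_prefix = "w",
                       seed = 1) {
  if (nrow(bout_schedule) && any(bout_schedule$freq >= fps / 2))
    stop("bout frequencies must stay below fps/2")
  miss <- if (length(missing_rate) == 1)
    stats::setNames(rep(missing_rate, 7), KEYPOINTS)
  else {
    m <- stats::setNames(rep(0, 7), KEYPOINTS)
    m[names(missing_rate)] <- missing_rate
    m
  }
  with_seed(seed, {
    n <- round(duration_s * fps)
    t <- (seq_len(n) - 1) / fps
    tracks <- vector("list", n_worms)
    truth <- list()
    for (w in seq_len(n_worms)) {
      wid <- sprintf("%s%02d", worm_prefix, w)
      x <- matrix(rep(20 * (1:7), each = n), n, 7,
                  dimnames = list(NULL, KEYPOINTS))
      y <- matrix(50, n, 7, dimnames = list(NULL, KEYPOINTS))
      phases <- stats::runif(5, 0, 2 * pi)
      if (nrow(bout_schedule)) for (b in seq_len(nrow(bout_schedule))) {
        inb <- t >= bout_schedule$start[b] & t < bout_schedule$end[b]
        for (p in seq_along(BODY_POINTS)) {
          y[inb, BODY_POINTS[p]] <- y[inb, BODY_POINTS[p]] +
            bout_schedule$amp[b] *
            sin(2 * pi * bout_schedule$freq[b] *
                  (t[inb] - bout_schedule$start[b]) + phases[p])
        }
      }
      if (drift_px_per_s != 0) {
        x <- x + drift_px_per_s * t
        y <- y + drift_px_per_s * t
      }
      present <- matrix(TRUE, n, 7, dimnames = list(NULL, KEYPOINTS))
      for (p in KEYPOINTS) if (miss[p] > 0)
        present[, p] <- stats::runif(n) >= miss[p]
      tracks[[w]] <- keypoint_track(wid, x, y, present, fps = fps,
                                    genotype = genotype, t0 = t0)
      nwin <- n %/% round(10 * fps)
      ws <- (seq_len(nwin) - 1) * 10
      if (nrow(bout_schedule)) {
        covered <- vapply(ws, function(s0) any(
          bout_schedule$start <= s0 & bout_schedule$end >= s0 + 10),
          logical(1))
        touched <- vapply(ws, function(s0) any(
          bout_schedule$start < s0 + 10 & bout_schedule$end > s0),
          logical(1))
        lab <- ifelse(covered, TRUE, ifelse(!touched, FALSE, NA))
      } else lab <- rep(FALSE, nwin)
      truth[[w]] <- data.frame(worm_id = wid, window_index = seq_len(nwin),
                               start_time = ws, undulating = lab,
                               boundary = is.na(lab))
    }
    list(tracks = tracks, truth = do.call(rbind, truth))
  })
}
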
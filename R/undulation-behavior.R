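#' @title Keypoint tracks and undulation-behavior analysis
#' @name undulation
#' @description
#' Tools to turn 7-point keypoint trajectories of worm trunks (jaws,
#' body1-body5, tail) into per-window undulation calls, binned
#' undulation-ratio time series, per-animal AUC over circadian
#' intervals, and nonparametric group comparisons.
NULL

KEYPOINTS <- c("jaws", "body1", "body2", "body3", "body4", "body5", "tail")
BODY_POINTS <- paste0("body", 1:5)

#' Construct a keypoint track
#'
#' @param worm_id Animal identifier.
#' @param x,y Numeric matrices, frames in rows, the 7 named keypoints
#'   (`jaws`, `body1`..`body5`, `tail`) in columns.
#' @param present Logical matrix, same shape: whether the point was
#'   annotated in that frame.
#' @param fps Frames per second (> 0).
#' @param genotype Group label (default `"wt"`).
#' @param t0 Recording start in zeitgeber/circadian time, hours
#'   (default 0).
#' @return Object of class `keypoint_track`.
#' @export
keypoint_track <- function(worm_id, x, y, present = NULL, fps = 5,
                           genotype = "wt", t0 = 0) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(present)) present <- !is.na(x) & !is.na(y)
  present <- as.matrix(present)
  stopifnot(fps > 0, identical(dim(x), dim(y)),
            identical(dim(x), dim(present)))
  if (is.null(colnames(x)) || !setequal(colnames(x), KEYPOINTS))
    stop("x/y must have the 7 keypoint columns: ",
         paste(KEYPOINTS, collapse = ", "))
  y <- y[, colnames(x), drop = FALSE]
  present <- present[, colnames(x), drop = FALSE]
  structure(list(worm_id = as.character(worm_id), genotype = genotype,
                 fps = as.numeric(fps), t0 = as.numeric(t0),
                 x = x, y = y, present = present),
            class = "keypoint_track")
}

#' Coverage-based track quality control
#'
#' A track is retained only when every one of its 7 keypoints is
#' annotated in at least `min_coverage` of the frames.
#'
#' @param tracks List of `keypoint_track` objects.
#' @param min_coverage Minimum per-point presence fraction (default
#'   0.9).
#' @return The retained tracks (possibly empty list).
#' @export
qc_tracks <- function(tracks, min_coverage = 0.9) {
  keep <- vapply(tracks, function(tr) {
    all(colMeans(tr$present) >= min_coverage)
  }, logical(1))
  tracks[keep]
}

#' Fill missing keypoint coordinates
#'
#' Interior gaps are filled by per-coordinate linear interpolation
#' between the flanking annotated frames; leading and trailing gaps are
#' extended with the nearest observed value (interpolation is undefined
#' there).
#'
#' @param track A `keypoint_track`.
#' @return The track with all frames present.
#' @export
interpolate_missing <- function(track) {
  n <- nrow(track$x)
  idx <- seq_len(n)
  for (p in colnames(track$x)) {
    obs <- which(track$present[, p])
    if (!length(obs))
      stop("keypoint ", p, " of ", track$worm_id, " has no observed frames")
    if (length(obs) < n) {
      for (coord in c("x", "y")) {
        v <- track[[coord]][obs, p]
        track[[coord]][, p] <- if (length(obs) == 1) v else
          stats::approx(obs, v, xout = idx, rule = 2)$y
      }
    }
  }
  track$present[] <- TRUE
  track
}

# Raw periodogram of one mean-removed signal: power per nonnegative
# frequency bin, DC included at index 1 (callers exclude it).
periodogram_power <- function(v, fps) {
  n <- length(v)
  P <- Mod(stats::fft(v - mean(v)))^2 / n
  nf <- floor(n / 2) + 1L
  list(freq = (seq_len(nf) - 1L) * fps / n, power = P[seq_len(nf)])
}

#' Classify one 10-second window as undulatory or not
#'
#' For each of the five trunk points (`body1`..`body5`) a mean-removed
#' periodogram is computed per coordinate axis; the point's dominant
#' frequency is the peak bin (DC excluded) of the axis with the larger
#' peak power, and its movement is the larger of the two axes'
#' peak-to-peak coordinate ranges. The window counts as undulation if
#' ANY of the five points moves within `move_band` pixels (inclusive)
#' AND has a dominant frequency within `freq_band` Hz (inclusive).
#'
#' @param x,y Numeric matrices of the window's frames (rows) by the
#'   five body points (columns `body1`..`body5`; extra columns are
#'   ignored).
#' @param fps Frames per second; must satisfy the Nyquist bound
#'   `fps >= 2 * freq_band[2]`.
#' @param freq_band Dominant-frequency band in Hz (default 0.5-1.5).
#' @param move_band Movement band in pixels (default 0.5-10).
#' @param window_s Expected window duration in s (default 10); the
#'   frame count must equal `round(window_s * fps)`.
#' @return List with `undulating` (logical), and per-point
#'   `dominant_frequency` (Hz) and `movement` (px).
#' @export
classify_window <- function(x, y, fps, freq_band = c(0.5, 1.5),
                            move_band = c(0.5, 10), window_s = 10) {
  x <- as.matrix(x); y <- as.matrix(y)
  pts <- intersect(BODY_POINTS, colnames(x))
  if (length(pts) != 5)
    stop("window must contain the five columns body1..body5")
  if (nrow(x) != round(window_s * fps))
    stop("window must span exactly ", window_s, " s (",
         round(window_s * fps), " frames at ", fps, " fps)")
  if (fps < 2 * freq_band[2])
    stop("fps below the Nyquist bound for the frequency band")
  domfreq <- movement <- stats::setNames(numeric(5), pts)
  for (p in pts) {
    px <- periodogram_power(x[, p], fps)
    py <- periodogram_power(y[, p], fps)
    # drop DC, pick the axis with the larger peak power
    kx <- which.max(px$power[-1]) + 1L
    ky <- which.max(py$power[-1]) + 1L
    domfreq[p] <- if (px$power[kx] >= py$power[ky]) px$freq[kx] else py$freq[ky]
    movement[p] <- max(diff(range(x[, p])), diff(range(y[, p])))
  }
  hit <- movement >= move_band[1] & movement <= move_band[2] &
    domfreq >= freq_band[1] & domfreq <= freq_band[2]
  list(undulating = any(hit), dominant_frequency = domfreq,
       movement = movement)
}

#' Classify every 10-second window of a track
#'
#' Splits a (gap-filled) track into consecutive non-overlapping windows
#' aligned to the recording start and classifies each with
#' [classify_window()]. A trailing partial window is dropped.
#'
#' @param track A `keypoint_track` with no missing frames.
#' @inheritParams classify_window
#' @return data.frame with `window_index`, `start_time` (s),
#'   `undulating`, and per-point `freq_*` / `move_*` columns.
#' @export
classify_track <- function(track, freq_band = c(0.5, 1.5),
                           move_band = c(0.5, 10), window_s = 10) {
  wlen <- round(window_s * track$fps)
  nwin <- nrow(track$x) %/% wlen
  if (!nwin) stop("track shorter than one window")
  rows <- vector("list", nwin)
  for (w in seq_len(nwin)) {
    fr <- ((w - 1L) * wlen + 1L):(w * wlen)
    cl <- classify_window(track$x[fr, BODY_POINTS],
                          track$y[fr, BODY_POINTS], track$fps,
                          freq_band, move_band, window_s)
    rows[[w]] <- data.frame(window_index = w,
                            start_time = (w - 1) * window_s,
                            undulating = cl$undulating,
                            t(c(stats::setNames(cl$dominant_frequency,
                                                paste0("freq_", BODY_POINTS)),
                                stats::setNames(cl$movement,
                                                paste0("move_", BODY_POINTS)))))
  }
  do.call(rbind, rows)
}

#' Undulation-ratio time series
#'
#' Fraction of 10-second windows classified as undulation per
#' consecutive time bin (default 3 min). Bins containing no windows are
#' omitted.
#'
#' @param classifications data.frame from [classify_track()]
#'   (time-ordered, non-overlapping windows).
#' @param bin_width Bin width in seconds (default 180).
#' @return data.frame with `bin_start` (s), `ratio` in \[0, 1\],
#'   `n_windows`.
#' @export
undulation_ratio <- function(classifications, bin_width = 180) {
  bin <- floor(classifications$start_time / bin_width) * bin_width
  agg <- stats::aggregate(classifications$undulating, list(bin_start = bin),
                          function(u) c(mean(u), length(u)))
  data.frame(bin_start = agg$bin_start, ratio = agg$x[, 1],
             n_windows = as.integer(agg$x[, 2]))
}

#' Area under the undulation-ratio curve over a time interval
#'
#' Trapezoidal integral of the ratio series over `[t_start, t_end]`
#' hours, with linear interpolation at the interval endpoints. The
#' series' bin midpoints are placed on the absolute (zeitgeber or
#' circadian) time axis via the track's recording start `t0`.
#'
#' @param series data.frame from [undulation_ratio()].
#' @param t_start,t_end Interval bounds in hours.
#' @param t0 Recording start in hours (default 0).
#' @param bin_width Bin width in seconds used to build the series
#'   (default 180); the ratio of a bin is placed at its midpoint.
#' @return Scalar AUC in ratio x hours.
#' @export
interval_auc <- function(series, t_start, t_end, t0 = 0,
                         bin_width = 180) {
  stopifnot(t_end > t_start)
  t_h <- t0 + (series$bin_start + bin_width / 2) / 3600
  r <- series$ratio[order(t_h)]
  t_h <- sort(t_h)
  if (max(t_h) <= t_start || min(t_h) >= t_end)
    stop("ratio series does not overlap the requested interval")
  lo <- max(t_start, min(t_h)); hi <- min(t_end, max(t_h))
  grid <- unique(sort(c(lo, hi, t_h[t_h > lo & t_h < hi])))
  v <- stats::approx(t_h, r, xout = grid)$y
  sum(diff(grid) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Nonparametric comparison of per-animal AUC values
#'
#' For each group, a Shapiro-Wilk normality test; for within-genotype
#' light-vs-dark contrasts, a paired Wilcoxon signed-rank test; for
#' between-genotype contrasts within a condition, an unpaired Wilcoxon
#' rank-sum test. Wilcoxon tests use the large-sample statistic without
#' continuity correction (tied AUC values are common, so the exact null
#' is unavailable anyway). When all paired differences are zero the
#' signed-rank test is degenerate and reported as p = 1 with a flag.
#'
#' @param auc data.frame with columns `worm_id`, `genotype`,
#'   `condition`, `auc`; paired contrasts match rows by `worm_id`.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return data.frame with `test_name`, `contrast`, `statistic`,
#'   `p_value`, `n`, `paired`, `significant`, `degenerate`.
#' @export
compare_groups <- function(auc, alpha = 0.05) {
  stopifnot(all(c("worm_id", "genotype", "condition", "auc") %in%
                  names(auc)))
  rows <- list()
  add <- function(test, contrast, stat, p, n, paired, degen = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test_name = test, contrast = contrast, statistic = stat,
      p_value = p, n = n, paired = paired,
      significant = p < alpha, degenerate = degen)
  }
  for (g in unique(auc$genotype)) for (cond in unique(auc$condition)) {
    v <- auc$auc[auc$genotype == g & auc$condition == cond]
    if (length(v) >= 3 && length(unique(v)) > 1) {
      sw <- stats::shapiro.test(v)
      add("shapiro", paste(g, cond, sep = "/"), unname(sw$statistic),
          sw$p.value, length(v), FALSE)
    }
  }
  conds <- unique(auc$condition)
  if (length(conds) == 2) {
    for (g in unique(auc$genotype)) {
      a <- auc[auc$genotype == g & auc$condition == conds[1], ]
      b <- auc[auc$genotype == g & auc$condition == conds[2], ]
      common <- intersect(a$worm_id, b$worm_id)
      if (length(common) >= 3) {
        d <- a$auc[match(common, a$worm_id)] -
          b$auc[match(common, b$worm_id)]
        if (all(d == 0)) {
          add("wilcoxon_signed_rank",
              paste0(g, ": ", conds[1], " vs ", conds[2]),
              NA_real_, 1, length(common), TRUE, degen = TRUE)
        } else {
          wt <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)
          add("wilcoxon_signed_rank",
              paste0(g, ": ", conds[1], " vs ", conds[2]),
              unname(wt$statistic), wt$p.value, length(common), TRUE)
        }
      }
    }
  }
  gts <- unique(auc$genotype)
  if (length(gts) == 2) {
    for (cond in conds) {
      a <- auc$auc[auc$genotype == gts[1] & auc$condition == cond]
      b <- auc$auc[auc$genotype == gts[2] & auc$condition == cond]
      if (length(a) >= 3 && length(b) >= 3) {
        wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
        add("wilcoxon_rank_sum",
            paste0(cond, ": ", gts[1], " vs ", gts[2]),
            unname(wt$statistic), wt$p.value, length(a) + length(b),
            FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write / read keypoint tracks as long-format CSV
#'
#' Columns: `worm_id`, `frame`, `point_name`, `x`, `y`, `present`.
#' Per-track metadata (`fps`, `genotype`, `t0`) travels in a separate
#' metadata data.frame (one row per worm) written alongside.
#'
#' @param tracks List of `keypoint_track` objects.
#' @param path CSV path for the coordinate table.
#' @param meta_path CSV path for the metadata table.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, meta_path) {
  long <- do.call(rbind, lapply(tracks, function(tr) {
    n <- nrow(tr$x)
    do.call(rbind, lapply(KEYPOINTS, function(p) {
      data.frame(worm_id = tr$worm_id, frame = seq_len(n),
                 point_name = p, x = tr$x[, p], y = tr$y[, p],
                 present = as.integer(tr$present[, p]))
    }))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  meta <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(worm_id = tr$worm_id, fps = tr$fps,
               genotype = tr$genotype, t0 = tr$t0)
  }))
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, meta_path) {
  long <- utils::read.csv(path)
  meta <- utils::read.csv(meta_path)
  lapply(split(long, long$worm_id), function(d) {
    nfr <- max(d$frame)
    x <- y <- matrix(NA_real_, nfr, 7, dimnames = list(NULL, KEYPOINTS))
    pr <- matrix(FALSE, nfr, 7, dimnames = list(NULL, KEYPOINTS))
    for (p in KEYPOINTS) {
      dp <- d[d$point_name == p, ]
      x[dp$frame, p] <- dp$x
      y[dp$frame, p] <- dp$y
      pr[dp$frame, p] <- dp$present == 1
    }
    m <- meta[meta$worm_id == d$worm_id[1], ]
    keypoint_track(d$worm_id[1], x, y, pr, fps = m$fps,
                   genotype = m$genotype, t0 = m$t0)
  })
}
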
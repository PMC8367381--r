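blank_track <- function(n = 100, fps = 5, worm_id = "w1") {
  x <- matrix(rep(20 * (1:7), each = n), n, 7,
              dimnames = list(NULL, c("jaws", paste0("body", 1:5), "tail")))
  y <- matrix(50, n, 7, dimnames = dimnames(x))
  keypoint_track(worm_id, x, y, fps = fps)
}

test_that("coverage QC excludes tracks with any under-annotated point", {
  tr <- blank_track(100)
  tr$present[1:11, "body2"] <- FALSE            # 89% coverage on one point
  expect_length(qc_tracks(list(tr)), 0)
  expect_length(qc_tracks(list(blank_track())), 1)
  none <- blank_track()
  none$present[] <- FALSE
  expect_length(qc_tracks(list(none)), 0)
  # exactly 90% is retained (inclusive threshold)
  edge <- blank_track(100)
  edge$present[1:10, "body2"] <- FALSE
  expect_length(qc_tracks(list(edge)), 1)
})

test_that("gap filling interpolates interior gaps and extends the edges", {
  tr <- blank_track(20)
  expect_identical(interpolate_missing(tr)$x, tr$x)   # no gaps: identity

  tr$x[11, "body3"] <- tr$y[11, "body3"] <- NA
  tr$present[11, "body3"] <- FALSE
  tr$x[10, "body3"] <- 0; tr$y[10, "body3"] <- 0
  tr$x[12, "body3"] <- 2; tr$y[12, "body3"] <- 2
  filled <- interpolate_missing(tr)
  expect_equal(unname(filled$x[11, "body3"]), 1)
  expect_equal(unname(filled$y[11, "body3"]), 1)

  lead <- blank_track(20)
  lead$present[1:5, "body1"] <- FALSE
  lead$x[1:5, "body1"] <- NA
  lead$x[6, "body1"] <- 5; lead$y[6, "body1"] <- 5
  f2 <- interpolate_missing(lead)
  expect_true(all(f2$x[1:5, "body1"] == 5))

  gone <- blank_track(20)
  gone$present[, "tail"] <- FALSE
  expect_error(interpolate_missing(gone), "tail")
})

test_that("window classification implements the frequency and movement bands", {
  still <- sine_window(freq = 1, amp = 0)
  expect_false(classify_window(still$x, still$y, still$fps)$undulating)

  w <- sine_window(freq = 1, amp = 2)           # 4 px peak-to-peak
  cl <- classify_window(w$x, w$y, w$fps)
  expect_true(cl$undulating)
  expect_equal(unname(cl$dominant_frequency["body3"]), 1.0)

  fast <- sine_window(freq = 3, amp = 2)        # above 1.5 Hz
  expect_false(classify_window(fast$x, fast$y, fast$fps)$undulating)

  big <- sine_window(freq = 1, amp = 15)        # 30 px peak-to-peak
  clb <- classify_window(big$x, big$y, big$fps)
  expect_false(clb$undulating)
  expect_gt(clb$movement["body3"], 10)

  expect_error(classify_window(w$x[1:50, ], w$y[1:50, ], w$fps),
               "exactly 10")
  slow <- sine_window(freq = 0.5, amp = 2, fps = 2)  # 20-frame window
  expect_error(classify_window(slow$x, slow$y, fps = 2), "Nyquist")
})

test_that("classification is translation-invariant and point-exchangeable", {
  w <- sine_window(freq = 1, amp = 2, point = "body3")
  shifted_x <- w$x + 137.5
  shifted_y <- w$y - 42
  a <- classify_window(w$x, w$y, w$fps)
  b <- classify_window(shifted_x, shifted_y, w$fps)
  expect_identical(a$undulating, b$undulating)
  expect_equal(a$dominant_frequency, b$dominant_frequency)
  for (p in paste0("body", c(1, 5))) {
    wp <- sine_window(freq = 1, amp = 2, point = p)
    expect_true(classify_window(wp$x, wp$y, wp$fps)$undulating)
  }
})

test_that("undulation ratio counts undulating windows per bin", {
  cls <- data.frame(window_index = 1:18, start_time = (0:17) * 10,
                    undulating = rep(c(TRUE, FALSE), 9))
  r <- undulation_ratio(cls)                    # all in one 180 s bin
  expect_identical(nrow(r), 1L)
  expect_equal(r$ratio, 0.5)
  all_on <- transform(cls, undulating = TRUE)
  expect_true(all(undulation_ratio(all_on)$ratio == 1))
  all_off <- transform(cls, undulating = FALSE)
  expect_true(all(undulation_ratio(all_off)$ratio == 0))
})

test_that("interval AUC integrates the ratio over hours", {
  # constant 1 over a series whose support covers the 8-hour interval
  n <- 8 * 3600 / 180 + 3
  series <- data.frame(bin_start = (0:(n - 1)) * 180,
                       ratio = 1, n_windows = 18)
  expect_equal(interval_auc(series, 0.1, 8.1), 8, tolerance = 1e-6)
  expect_equal(interval_auc(transform(series, ratio = 0), 0.1, 8.1), 0)
  ramp <- transform(series,
                    ratio = seq(0, 1, length.out = n))
  t_mid <- (series$bin_start + 90) / 3600
  expect_equal(interval_auc(ramp, min(t_mid), max(t_mid)),
               (max(t_mid) - min(t_mid)) / 2, tolerance = 1e-6)
  expect_error(interval_auc(series, 20, 24), "overlap")
})

test_that("group comparisons run the Shapiro/Wilcoxon battery", {
  set.seed(71)
  auc <- rbind(
    data.frame(worm_id = paste0("w", 1:10), genotype = "wt",
               condition = "day", auc = 1:10),
    data.frame(worm_id = paste0("w", 1:10), genotype = "mut",
               condition = "day", auc = 1:10))
  cmp <- compare_groups(auc)
  rs <- cmp[cmp$test_name == "wilcoxon_rank_sum", ]
  expect_gte(rs$p_value, 0.99)                  # identical groups

  sep <- auc
  sep$auc[sep$genotype == "mut"] <- 101:110     # disjoint ranges
  rs2 <- compare_groups(sep)
  rs2 <- rs2[rs2$test_name == "wilcoxon_rank_sum", ]
  expect_lt(rs2$p_value, 0.001)
  # exact-enumeration oracle: full separation is the extreme table
  expect_gte(rs2$p_value, 2 * stats::pwilcox(0, 10, 10))

  paired <- rbind(
    data.frame(worm_id = paste0("w", 1:8), genotype = "wt",
               condition = "day", auc = 3),
    data.frame(worm_id = paste0("w", 1:8), genotype = "wt",
               condition = "subjective_day", auc = 3))
  pc <- compare_groups(paired)
  sr <- pc[pc$test_name == "wilcoxon_signed_rank", ]
  expect_equal(sr$p_value, 1)
  expect_true(sr$degenerate)
})

test_that("scheduled synthetic bouts are classified correctly away from edges", {
  sched <- data.frame(start = c(30, 300), end = c(150, 450),
                      freq = 1, amp = 1.5)
  g <- gen_tracks(n_worms = 2, fps = 5, duration_s = 600,
                  bout_schedule = sched, drift_px_per_s = 0.02,
                  seed = 14)
  for (i in 1:2) {
    cls <- classify_track(g$tracks[[i]])
    truth <- g$truth[g$truth$worm_id == g$tracks[[i]]$worm_id, ]
    clear <- !truth$boundary
    expect_identical(cls$undulating[clear], truth$undulating[clear])
  }
  # ratio per 180 s bin tracks the scheduled bout coverage within one
  # window's worth of edge error
  r <- undulation_ratio(classify_track(g$tracks[[1]]))
  coverage <- function(lo, hi) {
    sum(pmax(0, pmin(hi, sched$end) - pmax(lo, sched$start))) / (hi - lo)
  }
  for (i in seq_len(nrow(r))) {
    span <- min(600, r$bin_start[i] + 180) - r$bin_start[i]
    expect_lte(abs(r$ratio[i] - coverage(r$bin_start[i],
                                         r$bin_start[i] + span)),
               2 * 10 / span)
  }
})

test_that("tracks with excessive missingness are excluded, others interpolable", {
  g <- gen_tracks(n_worms = 1, duration_s = 200,
                  missing_rate = c(body2 = 0.15), seed = 4)
  expect_length(qc_tracks(g$tracks), 0)
  g2 <- gen_tracks(n_worms = 1, duration_s = 200,
                   missing_rate = c(body2 = 0.05), seed = 4)
  kept <- qc_tracks(g2$tracks)
  expect_length(kept, 1)
  filled <- interpolate_missing(kept[[1]])
  expect_true(all(filled$present))
  expect_false(anyNA(filled$x))
})

test_that("track CSV round-trips with metadata", {
  g <- gen_tracks(n_worms = 2, duration_s = 100, seed = 6,
                  genotype = "mut", t0 = 6)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_tracks(g$tracks, p1, p2)
  back <- read_tracks(p1, p2)
  tr <- back[[g$tracks[[1]]$worm_id]]
  expect_equal(tr$x, g$tracks[[1]]$x)
  expect_identical(tr$genotype, "mut")
  expect_identical(tr$fps, 5)
})
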
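flat_tm <- function(val = 100, n = 200, fs = 2, rois = 1,
                    kind = "calcium_culture") {
  trace_matrix(matrix(val, rois, n), fs, kind)
}

test_that("dF/F0 normalization recovers steps and rejects bad baselines", {
  # constant trace -> all zeros
  z <- normalize_dff(flat_tm(), baseline_window_s = 30)
  expect_true(all(abs(z$traces) < 1e-12))
  # +20% step on a constant baseline -> plateau 0.20 within 1%
  v <- c(rep(100, 300), rep(120, 40), rep(100, 300))
  tm <- trace_matrix(matrix(v, 1), fs = 2, kind = "calcium_culture")
  dff <- normalize_dff(tm, baseline_window_s = 100)
  plateau <- dff$traces[1, 310:330]
  expect_true(all(abs(plateau - 0.20) / 0.20 < 0.01))
  expect_error(normalize_dff(trace_matrix(matrix(c(-1, rep(1, 99)), 1),
                                          2), 30), "positive")
  expect_error(normalize_dff(flat_tm(), baseline_window_s = 0.5),
               "3 frames")
})

test_that("peak detection recovers template amplitude and half-width", {
  # analytic template: instant rise, exponential decay, FWHM = 1 s
  fs <- 100
  tau <- 1 / log(2)
  t <- seq(0, 60, by = 1 / fs)
  bump <- function(t0) ifelse(t >= t0, 0.5 * exp(-(t - t0) / tau), 0)
  dff <- trace_matrix(matrix(bump(20) + bump(40), 1), fs,
                      "calcium_culture")
  pk <- detect_peaks(dff, min_amplitude = 0.15)
  expect_equal(nrow(pk$events), 2)  # separated bumps -> 2 events
  expect_true(all(abs(pk$events$amplitude - 0.5) / 0.5 < 0.01))
  expect_true(all(abs(pk$events$halfwidth_s - 1) / 1 < 0.015))
  # sub-threshold bump not detected
  small <- trace_matrix(matrix(0.10 * exp(-abs(t - 30)), 1), fs,
                        "calcium_culture")
  expect_equal(nrow(detect_peaks(small, min_amplitude = 0.15)$events), 0)
  # kind-specific defaults
  expect_equal(membranet:::.default_min_amplitude("calcium_slice"), 0.20)
  expect_equal(membranet:::.default_min_amplitude("glutamate"), 0.01)
})

test_that("MC threshold matches the analytic binomial null and is seeded", {
  set.seed(71)
  m <- matrix(rbinom(100 * 1200, 1, 0.01), 100, 1200)
  ra <- event_raster(m, fs = 2)
  th <- mc_coactivity_threshold(ra, n_perm = 500, seed = 5)
  expect_lte(abs(th - qbinom(0.999, 100, 0.01)), 1)
  expect_identical(th, mc_coactivity_threshold(ra, n_perm = 500,
                                               seed = 5))
  # 1 ROI: max co-activity is 1
  r1 <- event_raster(matrix(rbinom(300, 1, 0.05), 1), fs = 2)
  expect_lte(mc_coactivity_threshold(r1, n_perm = 100, seed = 1), 1L)
  # empty raster: threshold 0 with flag
  r0 <- event_raster(matrix(0, 3, 50), fs = 2)
  th0 <- mc_coactivity_threshold(r0, n_perm = 10, seed = 1)
  expect_equal(as.integer(th0), 0L)
  expect_equal(attr(th0, "flag"), "empty_raster")
})

test_that("null rasters rarely cross the MC threshold", {
  frac <- vapply(1:20, function(s) {
    set.seed(200 + s)
    m <- matrix(rbinom(60 * 600, 1, 0.01), 60, 600)
    ra <- event_raster(m, fs = 2)
    th <- mc_coactivity_threshold(ra, n_perm = 200, seed = s)
    mean(colSums(m) >= th)
  }, numeric(1))
  # pooled over seeds: the crossing rate stays at the permille level
  expect_lt(mean(frac), 0.005)
})

test_that("network-event segmentation counts distinct recruited ROIs", {
  m <- matrix(0L, 5, 30)
  m[1:4, 10] <- 1L          # one global co-active frame
  m[2, 11] <- 1L            # same run, one extra ROI
  m[5, 25] <- 1L            # isolated, below threshold
  ra <- event_raster(m, fs = 2)
  ne <- detect_network_events(ra, threshold = 3)
  expect_equal(nrow(ne$events), 1)
  expect_equal(ne$events$n_coactive, 4)  # distinct ROIs in the run
  expect_equal(ne$frequency_per_min, 1 / (30 / 2 / 60))
  # threshold above the maximum co-activity -> zero events
  expect_equal(nrow(detect_network_events(ra, threshold = 6)$events), 0)
})

test_that("planted network events are recovered with few spurious calls", {
  sens <- spur <- numeric(0)
  for (s in 1:10) {
    cfg <- syn_config(seed = 700 + s, n_rois = 80, duration_s = 300,
                      coactive_fraction = 0.4)
    g <- gen_traces(cfg)
    if (length(g$network_event_frames) == 0) next
    pk <- detect_peaks(normalize_dff(g$traces, 30))
    th <- mc_coactivity_threshold(pk, n_perm = 200, seed = s)
    ne <- detect_network_events(pk, max(th, 1))
    mm <- match_events(ne$events$start_frame, ne$events$end_frame,
                       g$network_event_frames)
    sens <- c(sens, mm$sensitivity); spur <- c(spur, mm$spurious)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(spur), 0.1)
})

test_that("pairwise correlation tracks planted synchrony", {
  # duplicated trace pair -> R = 1
  v <- rnorm(500)
  dup <- trace_matrix(rbind(v, v), 2, "calcium_culture")
  expect_equal(pairwise_correlation(dup)$mean_r, 1)
  # independent noise -> mean R ~ 0
  set.seed(81)
  ind <- trace_matrix(matrix(rnorm(4 * 10000), 4), 2, "calcium_culture")
  expect_lt(abs(pairwise_correlation(ind)$mean_r), 0.02)
  # mean R invariant to affine rescaling of a trace
  x <- trace_matrix(matrix(rnorm(3 * 500), 3), 2, "calcium_culture")
  y <- x; y$traces[2, ] <- 5 * y$traces[2, ] + 3
  expect_equal(pairwise_correlation(x)$mean_r,
               pairwise_correlation(y)$mean_r, tolerance = 1e-12)
  # monotone in coactive_fraction across three levels
  mr <- vapply(c(0.1, 0.4, 0.7), function(cf) {
    cfg <- syn_config(seed = 91, n_rois = 30, duration_s = 300,
                      coactive_fraction = cf)
    mean(vapply(1:3, function(s) {
      cfg$seed <- 90 + s
      pairwise_correlation(normalize_dff(gen_traces(cfg)$traces,
                                         30))$mean_r
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mr) > 0))
})

test_that("pairwise delay measures offsets and respects the window", {
  fs <- 10
  m <- matrix(0L, 2, 400)
  on <- seq(50, 350, by = 50)
  m[1, on] <- 1L
  m[2, on + 5] <- 1L  # 0.5 s offset
  pd <- pairwise_delay(event_raster(m, fs))
  expect_equal(pd$mean_delay_s, 0.5, tolerance = 1 / fs)
  # identical trains -> 0
  pd0 <- pairwise_delay(event_raster(rbind(m[1, ], m[1, ]), fs))
  expect_equal(pd0$mean_delay_s, 0)
  # offsets beyond the window exclude the pair
  m2 <- matrix(0L, 2, 400)
  m2[1, 50] <- 1L; m2[2, 200] <- 1L  # 15 s apart
  expect_true(is.na(pairwise_delay(event_raster(m2, fs))$mean_delay_s))
})

test_that("synchrony split is strict at the cut", {
  fs <- 10
  t <- seq(0, 120, by = 1 / fs)
  tr <- function(t0, a) ifelse(t >= t0, a * exp(-(t - t0) / 2), 0)
  # mixed planted peaks 0.1 / 0.4 split 1 and 1
  sp <- split_synchrony_events(tr(20, 0.1) + tr(80, 0.4), fs, cut = 0.2)
  expect_equal(nrow(sp$high), 1)
  expect_equal(nrow(sp$low), 1)
  # a peak exactly at the cut is assigned low (strict ">" for high)
  boundary <- split_synchrony_events(tr(40, 0.2), fs, cut = 0.2)
  expect_equal(nrow(boundary$high), 0)
  expect_equal(nrow(boundary$low), 1)
  all_high <- split_synchrony_events(tr(20, 0.3) + tr(60, 0.35), fs)
  expect_equal(nrow(all_high$low), 0)
  expect_equal(all_high$summary$frequency_per_min[1], 1,
               tolerance = 0.01)
})

test_that("evoked-response metrics match the analytic decay", {
  fs <- 20; tau <- 2
  t <- seq(0, 30, by = 1 / fs)
  base <- rep(100, 100)
  resp <- function(A) c(base, 100 * (1 + A * exp(-t / tau)))
  er <- evoked_response(resp(1), fs, stim_frame = 101)
  expect_equal(er$t_half_s, log(2) * tau, tolerance = 0.02)
  expect_equal(er$peak_amplitude, 1)
  # doubling A doubles amplitude and AUC, leaves t_half unchanged
  er2 <- evoked_response(resp(2), fs, stim_frame = 101)
  expect_equal(er2$peak_amplitude, 2 * er$peak_amplitude)
  expect_equal(er2$auc, 2 * er$auc, tolerance = 1e-9)
  expect_equal(er2$t_half_s, er$t_half_s, tolerance = 0.01)
  # flat post-stimulus trace: amplitude ~ 0, fit flagged
  flat <- evoked_response(rep(100, 400), fs, stim_frame = 101)
  expect_lt(abs(flat$peak_amplitude), 1e-9)
  expect_equal(flat$fit_flag, "no_fit")
})

test_that("trace CSV round-trips matrix, frame rate and kind", {
  cfg <- syn_config(seed = 95, n_rois = 3, duration_s = 30)
  tm <- gen_traces(cfg)$traces
  f <- tempfile(fileext = ".csv")
  write_traces_csv(tm, f)
  back <- read_traces_csv(f)
  expect_equal(back$traces, tm$traces, tolerance = 1e-8)
  expect_equal(back$fs, tm$fs)
  expect_equal(back$kind, tm$kind)
})
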
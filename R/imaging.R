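#' Fluorescence trace matrix
#'
#' @param traces numeric matrix, ROI x frame.
#' @param fs frame rate, frames/second.
#' @param kind recording kind: `"calcium_culture"`, `"calcium_slice"` or
#'   `"glutamate"`; sets the default peak-detection threshold.
#' @return object of class `"trace_matrix"`.
#' @export
trace_matrix <- function(traces, fs,
                         kind = c("calcium_culture", "calcium_slice",
                                  "glutamate")) {
  kind <- match.arg(kind)
  traces <- as.matrix(traces)
  if (ncol(traces) < 2) stop("trace_matrix: need at least 2 frames")
  if (fs <= 0) stop("trace_matrix: fs must be positive")
  structure(list(traces = traces, fs = fs, kind = kind),
            class = "trace_matrix")
}

#' Write / read trace matrices as wide CSV
#'
#' One row per ROI; the frame rate is stored in a leading comment line
#' `# fs=<frames/s> kind=<kind>`.
#'
#' @param tm a `"trace_matrix"`.
#' @param path file path.
#' @export
write_traces_csv <- function(tm, path) {
  stopifnot(inherits(tm, "trace_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g kind=%s", tm$fs, tm$kind), con)
  utils::write.table(tm$traces, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

#' @rdname write_traces_csv
#' @return [read_traces_csv()] returns a `"trace_matrix"`.
#' @export
read_traces_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", hdr))
  kind <- sub(".*kind=([a-z_]+).*", "\\1", hdr)
  m <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  trace_matrix(m, fs, kind)
}

#' Normalize raw traces to dF/F0
#'
#' The local baseline F0 is a running median over `baseline_window_s`
#' (median-filter baseline, robust to transients); the output is
#' `(F - F0) / F0`. Slice recordings are additionally smoothed with a
#' short symmetric FIR (binomial) kernel before normalization.
#'
#' @param raw a `"trace_matrix"` of positive raw fluorescence.
#' @param baseline_window_s baseline window in seconds (at least 3
#'   frames).
#' @return a `"trace_matrix"` in dF/F0 units.
#' @export
normalize_dff <- function(raw, baseline_window_s = 30) {
  stopifnot(inherits(raw, "trace_matrix"))
  win <- round(baseline_window_s * raw$fs)
  if (win < 3) stop("normalize_dff: baseline window below 3 frames")
  if (win %% 2 == 0) win <- win + 1
  x <- raw$traces
  if (any(x <= 0))
    stop("normalize_dff: raw traces must be positive")
  if (raw$kind == "calcium_slice") {
    k <- c(1, 4, 6, 4, 1) / 16  # binomial FIR smoothing kernel
    x <- t(apply(x, 1, function(v)
      stats::filter(c(rep(v[1], 2), v, rep(v[length(v)], 2)), k,
                    sides = 2)[3:(length(v) + 2)]))
  }
  win <- min(win, ncol(x) - (1 - ncol(x) %% 2))
  dff <- t(apply(x, 1, function(v) {
    f0 <- stats::runmed(v, win, endrule = "median")
    if (any(f0 <= 0)) stop("normalize_dff: baseline F0 <= 0")
    (v - f0) / f0
  }))
  trace_matrix(dff, raw$fs, raw$kind)
}

#' Construct an event raster directly
#'
#' Wraps a binary ROI x frame matrix (e.g. a simulated or externally
#' detected peak raster) in the `"event_raster"` container used by the
#' co-activation analytics.
#'
#' @param raster binary matrix, ROI x frame.
#' @param fs frame rate, frames/s.
#' @return an `"event_raster"` (event metadata carries NA amplitudes).
#' @export
event_raster <- function(raster, fs) {
  raster <- as.matrix(raster)
  stopifnot(all(raster %in% c(0, 1)), fs > 0)
  idx <- which(raster == 1L, arr.ind = TRUE)
  events <- data.frame(roi = as.integer(idx[, 1]),
                       peak_frame = as.integer(idx[, 2]),
                       amplitude = rep(NA_real_, nrow(idx)),
                       halfwidth_s = rep(NA_real_, nrow(idx)))
  events <- events[order(events$roi, events$peak_frame), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(raster = matrix(as.integer(raster), nrow(raster)),
                 events = events, fs = fs),
            class = "event_raster")
}

.default_min_amplitude <- function(kind) {
  switch(kind, calcium_culture = 0.15, calcium_slice = 0.20,
         glutamate = 0.01)
}

# Topographic prominence of local maxima: height above the higher of the
# two key saddles (the lowest point between the peak and the nearest
# higher ground on each side; the trace edge counts as higher ground at
# the global minimum).
.peak_prominence <- function(v, peaks) {
  vapply(peaks, function(i) {
    h <- v[i]
    left <- if (i == 1) h else {
      seg <- v[1:(i - 1)]
      higher <- which(seg > h)
      if (length(higher)) min(v[(max(higher) + 1):(i - 1)], h)
      else min(seg)
    }
    right <- if (i == length(v)) h else {
      seg <- v[(i + 1):length(v)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[1:(min(higher) - 1)], h)
      else min(seg)
    }
    h - max(left, right)
  }, numeric(1))
}

# half-prominence width of a peak by linear interpolation of crossings
.halfwidth_frames <- function(v, i, half) {
  n <- length(v)
  l <- i
  while (l > 1 && v[l] > half) l <- l - 1
  left <- if (v[l] > half) l else
    l + (half - v[l]) / (v[l + 1] - v[l])
  r <- i
  while (r < n && v[r] > half) r <- r + 1
  right <- if (v[r] > half) r else
    r - (half - v[r]) / (v[r - 1] - v[r])
  right - left
}

#' Detect fluorescence transients per ROI
#'
#' Local maxima of the dF/F0 trace with prominence (height above the
#' local baseline, which is ~0 after normalization) of at least
#' `min_amplitude`. The reported amplitude is the dF/F0 value at the
#' peak; the half-width is the width at half amplitude in seconds.
#'
#' @param dff a `"trace_matrix"` in dF/F0 units.
#' @param min_amplitude detection threshold in dF/F0; defaults by kind
#'   (0.15 culture, 0.20 slice, 0.01 glutamate).
#' @return object of class `"event_raster"`: list with `raster` (binary
#'   ROI x frame), `events` (data.frame roi, peak_frame, amplitude,
#'   halfwidth_s) and `fs`. An empty raster is allowed.
#' @export
detect_peaks <- function(dff, min_amplitude = NULL) {
  stopifnot(inherits(dff, "trace_matrix"))
  if (is.null(min_amplitude))
    min_amplitude <- .default_min_amplitude(dff$kind)
  stopifnot(min_amplitude > 0)
  x <- dff$traces
  n_rois <- nrow(x); n_frames <- ncol(x)
  raster <- matrix(0L, n_rois, n_frames)
  ev <- list()
  for (r in seq_len(n_rois)) {
    v <- x[r, ]
    # strict rise into the peak, non-increasing out of it (plateaus keep
    # the first frame); filter on topographic prominence so ripples on a
    # decay shoulder do not count as events
    is_pk <- which(diff(sign(diff(v))) < 0) + 1L
    is_pk <- is_pk[v[is_pk] >= min_amplitude]
    if (length(is_pk) > 0)
      is_pk <- is_pk[.peak_prominence(v, is_pk) >= min_amplitude]
    if (length(is_pk) > 0) {
      amp <- v[is_pk]
      hw <- vapply(seq_along(is_pk), function(j)
        .halfwidth_frames(v, is_pk[j], amp[j] / 2), numeric(1)) / dff$fs
      raster[r, is_pk] <- 1L
      ev[[length(ev) + 1L]] <- data.frame(
        roi = r, peak_frame = is_pk, amplitude = amp, halfwidth_s = hw)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(roi = integer(0), peak_frame = integer(0),
               amplitude = numeric(0), halfwidth_s = numeric(0))
  rownames(events) <- NULL
  structure(list(raster = raster, events = events, fs = dff$fs),
            class = "event_raster")
}

#' Monte-Carlo co-activation threshold
#'
#' Builds the null distribution of frame-wise co-active ROI counts by
#' redistributing each ROI's peak frames uniformly at random (the per-ROI
#' event count is preserved), `n_perm` times. The threshold is the
#' ceiling of the `pct` percentile of the pooled frame-wise counts over
#' all permutations — the minimal number of co-active cells that cannot
#' be explained by chance. A circular-shift null is available as an
#' alternative scheme.
#'
#' @param raster an `"event_raster"`.
#' @param n_perm number of permutations; default 1000.
#' @param pct percentile of the pooled null counts; default 99.9.
#' @param seed RNG seed; the threshold is deterministic given the seed.
#' @param scheme `"redistribute"` (default) or `"circular"` shift.
#' @return integer threshold; attribute `flag = "empty_raster"` and
#'   value 0 when the raster has no events.
#' @export
mc_coactivity_threshold <- function(raster, n_perm = 1000, pct = 99.9,
                                    seed = 1,
                                    scheme = c("redistribute",
                                               "circular")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(raster, "event_raster"), n_perm >= 1)
  m <- raster$raster
  counts_per_roi <- rowSums(m)
  n_frames <- ncol(m)
  if (sum(counts_per_roi) == 0)
    return(structure(0L, flag = "empty_raster"))
  active <- which(counts_per_roi > 0)
  pooled <- withr::with_seed(seed, {
    out <- integer(n_perm * n_frames)
    for (b in seq_len(n_perm)) {
      cnt <- integer(n_frames)
      for (r in active) {
        frames <- if (scheme == "redistribute") {
          sample.int(n_frames, counts_per_roi[r])
        } else {
          ((which(m[r, ] == 1L) - 1L +
              sample.int(n_frames, 1)) %% n_frames) + 1L
        }
        cnt[frames] <- cnt[frames] + 1L
      }
      out[(b - 1) * n_frames + seq_len(n_frames)] <- cnt
    }
    out
  })
  as.integer(ceiling(stats::quantile(pooled, pct / 100, names = FALSE,
                                     type = 1)))
}

#' Detect network (population) events
#'
#' Contiguous runs of frames whose co-active ROI count reaches the
#' threshold form one event each (no gap bridging). The event size is
#' the number of distinct ROIs peaking within the run.
#'
#' @param raster an `"event_raster"`.
#' @param threshold minimal co-active count, from
#'   [mc_coactivity_threshold()]; must be >= 1.
#' @return object of class `"network_event_set"`: list with `events`
#'   (data.frame start_frame, end_frame, n_coactive), `frequency_per_min`
#'   and `threshold`.
#' @export
detect_network_events <- function(raster, threshold) {
  stopifnot(inherits(raster, "event_raster"), threshold >= 1)
  m <- raster$raster
  cnt <- colSums(m)
  above <- cnt >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  events <- data.frame(start_frame = starts[sel], end_frame = ends[sel])
  events$n_coactive <- vapply(seq_len(nrow(events)), function(i)
    sum(rowSums(m[, events$start_frame[i]:events$end_frame[i],
                  drop = FALSE]) > 0), integer(1))
  minutes <- ncol(m) / raster$fs / 60
  structure(list(events = events,
                 frequency_per_min = nrow(events) / minutes,
                 threshold = as.integer(threshold)),
            class = "network_event_set")
}

#' Pairwise correlation synchrony
#'
#' Pearson correlation of continuous dF/F0 traces for every ROI pair.
#' Constant traces have undefined correlation; their pairs are excluded
#' and flagged. The summary is the mean of the upper triangle.
#'
#' @param dff a `"trace_matrix"` in dF/F0 units (>= 2 ROIs).
#' @return list with `pairwise_r` (symmetric matrix, unit diagonal),
#'   `mean_r` and `n_excluded_pairs`.
#' @export
pairwise_correlation <- function(dff) {
  stopifnot(inherits(dff, "trace_matrix"), nrow(dff$traces) >= 2)
  x <- t(dff$traces)
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  R <- suppressWarnings(stats::cor(x))
  diag(R) <- 1
  ut <- upper.tri(R)
  list(pairwise_r = R,
       mean_r = mean(R[ut], na.rm = TRUE),
       n_excluded_pairs = sum(is.na(R[ut])))
}

#' Mean nearest-event delay between ROI pairs
#'
#' For every event of ROI a, the nearest event of ROI b within
#' `± window_s` contributes its absolute time difference; pairs with no
#' in-window match are excluded. The summary is the mean over pairs of
#' the per-pair mean |delay|.
#'
#' @param raster an `"event_raster"`.
#' @param window_s matching window in seconds; default 2.1.
#' @return list with `pair_delays` (data.frame roi_a, roi_b,
#'   mean_abs_delay_s) and `mean_delay_s` (NA when no pair matches).
#' @export
pairwise_delay <- function(raster, window_s = 2.1) {
  stopifnot(inherits(raster, "event_raster"), window_s > 0)
  fs <- raster$fs
  times <- split(raster$events$peak_frame / fs, raster$events$roi)
  rois <- as.integer(names(times))
  out <- list()
  if (length(rois) >= 2) {
    for (i in seq_along(rois)[-length(rois)]) {
      for (j in (i + 1):length(rois)) {
        ta <- times[[i]]; tb <- times[[j]]
        d <- c(vapply(ta, function(t0) min(abs(tb - t0)), numeric(1)),
               vapply(tb, function(t0) min(abs(ta - t0)), numeric(1)))
        d <- d[d <= window_s]
        if (length(d) > 0)
          out[[length(out) + 1L]] <- data.frame(
            roi_a = rois[i], roi_b = rois[j], mean_abs_delay_s = mean(d))
      }
    }
  }
  pd <- if (length(out)) do.call(rbind, out) else
    data.frame(roi_a = integer(0), roi_b = integer(0),
               mean_abs_delay_s = numeric(0))
  list(pair_delays = pd,
       mean_delay_s = if (nrow(pd)) mean(pd$mean_abs_delay_s) else NA_real_)
}

#' Split population events into high and low synchrony classes
#'
#' Peaks of the population-mean dF/F0 trace are partitioned strictly by
#' amplitude: high if above `cut`, low otherwise (a peak exactly at the
#' cut is low).
#'
#' @param network_trace numeric vector, population-mean dF/F0 trace.
#' @param fs frame rate, frames/s.
#' @param cut amplitude cut in dF/F0; default 0.2.
#' @param min_amplitude detection threshold for the population peaks;
#'   default 0.01.
#' @return list with `high` and `low` (event data.frames) and
#'   `summary` (per-class n, mean amplitude, frequency/min, mean
#'   half-width).
#' @export
split_synchrony_events <- function(network_trace, fs, cut = 0.2,
                                   min_amplitude = 0.01) {
  tm <- trace_matrix(matrix(network_trace, nrow = 1), fs,
                     kind = "glutamate")
  pk <- detect_peaks(tm, min_amplitude = min_amplitude)
  ev <- pk$events
  hi <- ev[ev$amplitude > cut, , drop = FALSE]
  lo <- ev[ev$amplitude <= cut, , drop = FALSE]
  minutes <- length(network_trace) / fs / 60
  summarise <- function(e) data.frame(
    n = nrow(e),
    mean_amplitude = if (nrow(e)) mean(e$amplitude) else NA_real_,
    frequency_per_min = nrow(e) / minutes,
    mean_halfwidth_s = if (nrow(e)) mean(e$halfwidth_s) else NA_real_)
  list(high = hi, low = lo,
       summary = cbind(class = c("high", "low"),
                       rbind(summarise(hi), summarise(lo))))
}

#' Evoked-response metrics
#'
#' Normalizes a single trace to the mean of the first `baseline_frames`
#' frames (F/F0 - 1), then reports the post-stimulus peak amplitude, the
#' trapezoidal area under the response from the stimulus to the end of
#' the trace, and the decay half-life from a one-phase exponential fit
#' `y = A exp(-k t)` to the post-peak segment (`t_half = ln 2 / k`). If
#' the fit does not converge the half-life is NA with a flag.
#'
#' @param trace numeric vector, raw fluorescence of one ROI/FOV.
#' @param fs frame rate, frames/s.
#' @param stim_frame frame of stimulus delivery (> `baseline_frames`).
#' @param baseline_frames frames averaged for F0; default 50.
#' @return list with `peak_amplitude` (dF/F0), `auc` (dF/F0 * s),
#'   `t_half_s` and `fit_flag` (`"ok"` or `"no_fit"`).
#' @export
evoked_response <- function(trace, fs, stim_frame, baseline_frames = 50) {
  stopifnot(stim_frame > baseline_frames,
            stim_frame < length(trace))
  f0 <- mean(trace[seq_len(baseline_frames)])
  if (f0 <= 0) stop("evoked_response: baseline F0 <= 0")
  y <- trace / f0 - 1
  post <- y[stim_frame:length(y)]
  peak_rel <- which.max(post)
  amp <- post[peak_rel]
  tsec <- (seq_along(post) - 1) / fs
  auc <- sum(diff(tsec) * (post[-length(post)] + post[-1]) / 2)
  dec <- post[peak_rel:length(post)]
  tdec <- (seq_along(dec) - 1) / fs
  t_half <- NA_real_
  flag <- "no_fit"
  if (length(dec) >= 4 && amp > 0) {
    # log-linear starting values for the one-phase decay
    pos <- dec > amp * 1e-3
    k0 <- if (sum(pos) >= 3) {
      sl <- stats::coef(stats::lm(log(dec[pos]) ~ tdec[pos]))[2]
      max(-unname(sl), 1e-4)
    } else 1
    fit <- tryCatch(
      stats::nls(dec ~ A * exp(-kk * tdec),
                 start = list(A = amp, kk = k0),
                 control = stats::nls.control(maxiter = 200,
                                              scaleOffset = 1,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    kk <- if (!is.null(fit)) stats::coef(fit)[["kk"]] else NA_real_
    if (is.null(fit) && sum(pos) >= 3) {
      # noise-free decays have zero residual and defeat nls; the
      # log-linear estimator is exact there
      lf <- stats::lm(log(dec[pos]) ~ tdec[pos])
      if (summary(lf)$r.squared > 0.95) kk <- -unname(stats::coef(lf)[2])
    }
    if (is.finite(kk) && kk > 0) {
      t_half <- log(2) / kk
      flag <- "ok"
    }
  }
  list(peak_amplitude = amp, auc = auc, t_half_s = t_half,
       fit_flag = flag)
}
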
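#' Detect spikes on the AC trace by threshold search
#'
#' One spike per supra-threshold excursion, timestamped at the excursion
#' extremum; excursions starting within the refractory interval of an
#' accepted spike are suppressed. With `threshold = NULL` a robust noise
#' estimate (MAD-based SD, insensitive to the spikes themselves) sets the
#' threshold at `auto_factor` times the noise SD, and the dominant polarity
#' is chosen as the side with more supra-threshold extrema.
#'
#' @param ac AC sample vector (mV).
#' @param sampling_rate Hz.
#' @param threshold detection threshold in mV (> 0), or `NULL` for the
#'   noise-scaled automatic rule.
#' @param refractory minimal separation between accepted spikes (s).
#' @param polarity `"auto"`, `"positive"`, or `"negative"`.
#' @param auto_factor multiple of the noise SD for the automatic threshold.
#' @return object of class `spike_train`: list with `spike_times` (s,
#'   strictly increasing), `threshold_used` (mV), `polarity`.
#' @export
detect_spikes <- function(ac, sampling_rate, threshold = NULL,
                          refractory = 0.001,
                          polarity = c("auto", "positive", "negative"),
                          auto_factor = 4.5) {
  polarity <- match.arg(polarity)
  stopifnot(refractory >= 0, sampling_rate > 0)
  if (!is.null(threshold) && threshold <= 0) {
    stop("threshold must be positive (it is a magnitude)")
  }
  if (is.null(threshold)) {
    sigma <- stats::mad(ac)
    if (!is.finite(sigma) || sigma <= 0) {
      # noise-free trace: MAD is zero; if there are excursions at all,
      # half the largest magnitude separates spikes from the flat trace
      peak <- max(abs(ac - stats::median(ac)))
      if (!is.finite(peak) || peak <= 0) {
        stop("cannot estimate noise from a constant trace; ",
             "supply an explicit threshold")
      }
      threshold <- peak / 2
    } else {
      threshold <- auto_factor * sigma
    }
  }
  if (polarity == "auto") {
    # dominant polarity: the side whose supra-threshold extrema carry more
    # total amplitude above threshold (robust against noise splitting a
    # weak secondary lobe into several shallow excursions)
    ep <- excursion_extrema(ac, threshold)
    en <- excursion_extrema(-ac, threshold)
    polarity <- if (sum(-ac[en] - threshold) > sum(ac[ep] - threshold))
      "negative" else "positive"
  }
  x <- if (polarity == "negative") -ac else ac
  ext <- excursion_extrema(x, threshold)
  times <- (ext - 1) / sampling_rate
  # refractory suppression: keep the earliest spike of each conflict
  if (length(times) > 1 && refractory > 0) {
    times <- thin_refractory(times, refractory)
  }
  structure(list(spike_times = times, threshold_used = threshold,
                 polarity = polarity),
            class = "spike_train")
}

# indices of per-excursion maxima of x above +threshold
excursion_extrema <- function(x, threshold) {
  above <- x >= threshold
  if (!any(above)) return(integer(0))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(x[seg])]
  }, integer(1))
}

count_excursions <- function(x, threshold) {
  length(excursion_extrema(x, threshold))
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes, threshold %.3g mV (%s)\n",
              length(x$spike_times), x$threshold_used, x$polarity))
  invisible(x)
}

#' Detect the onset of the DC pheromone response
#'
#' The sensillum potential drops (negative deflection) when the pheromone
#' response starts. The criterion: relative to the median of a
#' pre-stimulus baseline window, find the first sample after the valve
#' opening whose smoothed DC value stays below
#' `baseline - max(k_sd * SD, min_drop)` (SD estimated by the baseline
#' MAD) for at least `sustain` seconds, then walk back along the rising
#' flank to the baseline level or the nearest local maximum. The trace is
#' smoothed with a short running median (default 5 ms) so spike waveforms
#' riding on the potential cannot trigger or bias the onset; on a monotone
#' noiseless onset the running median is exact. The result is invariant to
#' constant offsets of the whole trace.
#'
#' @param dc DC sample vector (mV).
#' @param stimulus_onset valve opening time (s).
#' @param sampling_rate Hz.
#' @param baseline_window seconds of baseline before the stimulus.
#' @param search_window seconds after the stimulus to search.
#' @param k_sd multiple of the baseline SD for the drop criterion.
#' @param min_drop noise floor (mV) for the drop criterion, so the
#'   criterion stays defined on noiseless traces.
#' @param sustain minimal duration (s) the trace must stay below threshold.
#' @param smooth_s running-median window (s); 0 disables smoothing.
#' @return onset time in seconds, or `NA` if no response is found.
#' @export
detect_response_onset <- function(dc, stimulus_onset, sampling_rate,
                                  baseline_window = 0.5,
                                  search_window = 0.2, k_sd = 3,
                                  min_drop = 0.01, sustain = 0.002,
                                  smooth_s = 0.005) {
  stim_idx <- round(stimulus_onset * sampling_rate) + 1L
  b0 <- stim_idx - round(baseline_window * sampling_rate)
  if (b0 < 1) stop("no pre-stimulus baseline window in the recording")
  end_idx <- stim_idx + round(search_window * sampling_rate)
  if (end_idx > length(dc)) {
    stop("search window extends past the end of the recording")
  }
  seg <- dc[b0:end_idx]
  seg <- smooth_dc(seg, sampling_rate, smooth_s)
  nb <- stim_idx - b0  # baseline samples within seg
  # median/MAD baseline: spike waveforms in the baseline window must not
  # shift the reference level or inflate the spread
  bctr <- stats::median(seg[seq_len(nb)])
  bsd <- stats::mad(seg[seq_len(nb)])
  thr <- bctr - max(k_sd * bsd, min_drop)
  post <- seg[(nb + 1):length(seg)]
  below <- post < thr
  need <- max(1L, round(sustain * sampling_rate))
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= need)
  if (!length(hit)) return(NA_real_)
  cross <- starts[hit[1]]
  # walk back from the crossing to the start of the deflection: follow the
  # trace backwards while it keeps rising towards baseline, stopping at
  # the baseline level or the nearest local maximum (so slow noise
  # wandering below baseline cannot drag the onset earlier)
  i <- cross
  while (i > 1 && post[i - 1] < bctr && post[i - 1] > post[i]) i <- i - 1
  (stim_idx - 1 + i - 1) / sampling_rate
}

smooth_dc <- function(x, sampling_rate, smooth_s) {
  if (smooth_s <= 0) return(x)
  k <- round(smooth_s * sampling_rate)
  if (k %% 2 == 0) k <- k + 1L
  if (k < 3 || k >= length(x)) return(x)
  as.numeric(stats::runmed(x, k, endrule = "keep"))
}

#' Compute the five per-stimulus response parameters
#'
#' Given the detected spike train and the DC trace of one stimulation
#' epoch:
#' * `latency_ms`: first spike after the response onset, minus the onset.
#' * `f6ap_hz`: mean of the five reciprocal inter-spike intervals of the
#'   first six spikes after onset; `NA` when fewer than six spikes occur
#'   within the first second.
#' * `spa_mv`: sensillum potential amplitude, the pre-stimulus baseline
#'   mean minus the minimum of the (median-smoothed) DC within the
#'   post-onset search window, reported as a non-negative magnitude.
#' * `n_aps_early`: spikes in `[onset, onset + early_window)`; the window
#'   is 1 s for the standard pharmacology protocol and 100 ms for paired
#'   toxin protocols.
#' * `n_aps_llpr` is computed separately by [compute_llpr_count()].
#'
#' @param spikes a `spike_train` from [detect_spikes()] (times in s).
#' @param dc DC sample vector.
#' @param sampling_rate Hz.
#' @param response_onset onset time (s) from [detect_response_onset()];
#'   `NA` yields all-missing features.
#' @param stimulus_onset valve opening time (s), anchors the SPA baseline.
#' @param early_window early count window (s), 1.0 or 0.1.
#' @param baseline_window SPA baseline window (s) before the stimulus.
#' @param spa_window SPA search window (s) after the response onset.
#' @param smooth_s running-median window (s) for the SPA measurement.
#' @return one-row data.frame with the feature columns.
#' @export
compute_response_features <- function(spikes, dc, sampling_rate,
                                      response_onset, stimulus_onset,
                                      early_window = 1.0,
                                      baseline_window = 0.5,
                                      spa_window = 1.0,
                                      smooth_s = 0.005) {
  if (early_window <= 0 || baseline_window <= 0 || spa_window <= 0) {
    stop("windows must be positive")
  }
  na_row <- data.frame(latency_ms = NA_real_, f6ap_hz = NA_real_,
                       spa_mv = NA_real_, n_aps_early = NA_integer_)
  if (is.na(response_onset)) return(na_row)
  st <- spikes$spike_times
  post <- st[st >= response_onset]
  latency <- if (length(post)) (post[1] - response_onset) * 1000 else NA_real_
  in1s <- post[post < response_onset + 1]
  f6 <- if (length(in1s) >= 6) mean(1 / diff(in1s[1:6])) else NA_real_
  # SPA on the smoothed DC, robust to spike waveforms riding on it
  stim_idx <- round(stimulus_onset * sampling_rate) + 1L
  b0 <- max(1L, stim_idx - round(baseline_window * sampling_rate))
  on_idx <- round(response_onset * sampling_rate) + 1L
  w1 <- min(length(dc), on_idx + round(spa_window * sampling_rate))
  seg <- smooth_dc(dc[b0:w1], sampling_rate, smooth_s)
  nb <- stim_idx - b0
  spa <- if (nb >= 1 && w1 > on_idx) {
    mean(seg[seq_len(nb)]) - min(seg[(on_idx - b0 + 1):(w1 - b0 + 1)])
  } else NA_real_
  data.frame(latency_ms = latency, f6ap_hz = f6, spa_mv = spa,
             n_aps_early = sum(post >= response_onset &
                                 post < response_onset + early_window))
}

#' Count spikes of the late long-lasting response
#'
#' Counts spikes from `exclusion` seconds after a stimulus up to the next
#' stimulus; at the standard 5-minute inter-stimulus interval with the
#' default 5 s exclusion this is the 295 s window before the next stimulus.
#'
#' @param spikes a `spike_train` or numeric vector of spike times (s).
#' @param stimulus_onset,next_stimulus_onset bracketing stimulus times (s).
#' @param exclusion seconds after `stimulus_onset` to exclude (default 5).
#' @return integer spike count in
#'   `[stimulus_onset + exclusion, next_stimulus_onset)`.
#' @export
compute_llpr_count <- function(spikes, stimulus_onset, next_stimulus_onset,
                               exclusion = 5) {
  st <- if (inherits(spikes, "spike_train")) spikes$spike_times
  else as.numeric(spikes)
  if (next_stimulus_onset <= stimulus_onset + exclusion) {
    stop("next_stimulus_onset must exceed stimulus_onset + exclusion")
  }
  sum(st >= stimulus_onset + exclusion & st < next_stimulus_onset)
}

#' Extract the per-stimulus feature table from a recording
#'
#' Runs spike detection once on the whole AC trace, then for each scheduled
#' stimulus detects the DC response onset and computes the response
#' parameters. Stimuli whose onset cannot be detected (or that lack a
#' baseline window) get missing feature cells, mirroring the `NaN`
#' convention of deposited trial tables. The LLPR count for the last
#' stimulus uses one nominal inter-stimulus interval if the recording is
#' long enough, otherwise it is missing.
#'
#' @param rec an [ssr_recording()].
#' @param early_window early spike-count window (s).
#' @param threshold,refractory passed to [detect_spikes()].
#' @param llpr_exclusion seconds excluded after each stimulus.
#' @param ... further arguments to [detect_response_onset()].
#' @return data.frame feature table (one row per stimulus) with columns
#'   `experiment_id`, `stimulation_time_min`, `latency_ms`, `f6ap_hz`,
#'   `spa_mv`, `n_aps_early`, `n_aps_llpr`.
#' @export
extract_features <- function(rec, early_window = 1.0, threshold = NULL,
                             refractory = 0.001, llpr_exclusion = 5, ...) {
  stopifnot(inherits(rec, "ssr_recording"))
  fs <- rec$sampling_rate
  dur <- length(rec$dc) / fs
  spk <- detect_spikes(rec$ac, fs, threshold = threshold,
                       refractory = refractory)
  onsets <- rec$stimulus_onsets
  interval <- if (length(onsets) > 1) stats::median(diff(onsets)) else NA
  rows <- lapply(seq_along(onsets), function(i) {
    ro <- tryCatch(
      detect_response_onset(rec$dc, onsets[i], fs, ...),
      error = function(e) NA_real_)
    feats <- compute_response_features(spk, rec$dc, fs, ro, onsets[i],
                                       early_window = early_window)
    nxt <- if (i < length(onsets)) onsets[i + 1]
    else if (!is.na(interval) && onsets[i] + interval <= dur + 1e-9)
      onsets[i] + interval
    else NA
    feats$n_aps_llpr <- if (!is.na(nxt) &&
                              nxt > onsets[i] + llpr_exclusion) {
      compute_llpr_count(spk, onsets[i], nxt, llpr_exclusion)
    } else NA_integer_
    cbind(data.frame(stimulation_time_min = onsets[i] / 60), feats)
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(experiment_id = rec$meta$animal_id %||% "rec"), out)
}

#' Extract features from epoch-rendered recordings
#'
#' Applies per-epoch spike detection and feature computation to the output
#' of `generate_recording(..., render = "epochs")`. The LLPR count is not
#' available from short epochs and is returned missing.
#'
#' @param epochs list of single-stimulus [ssr_recording()] epochs.
#' @inheritParams extract_features
#' @return data.frame feature table, one row per epoch.
#' @export
extract_features_epochs <- function(epochs, early_window = 1.0,
                                    threshold = NULL, refractory = 0.001,
                                    ...) {
  rows <- lapply(epochs, function(ep) {
    fs <- ep$sampling_rate
    spk <- detect_spikes(ep$ac, fs, threshold = threshold,
                         refractory = refractory)
    ro <- tryCatch(
      detect_response_onset(ep$dc, ep$stimulus_onsets[1], fs, ...),
      error = function(e) NA_real_)
    feats <- compute_response_features(spk, ep$dc, fs, ro,
                                       ep$stimulus_onsets[1],
                                       early_window = early_window)
    feats$n_aps_llpr <- NA_integer_
    cbind(data.frame(
      experiment_id = ep$meta$animal_id %||% "rec",
      stimulation_time_min = ep$meta$epoch_time_min %||% NA_real_),
      feats)
  })
  do.call(rbind, rows)
}
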
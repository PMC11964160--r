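#' Ground-truth parameters for a synthetic pheromone response
#'
#' Describes the stereotyped three-component spiking response of a
#' pheromone-sensitive olfactory receptor neuron to a brief stimulus: a
#' phasic high-frequency burst of about ten near-regular spikes lasting
#' under 100 ms, a slower and more variable tonic component of several
#' hundred milliseconds, a silent pause, and a late long-lasting response
#' (LLPR) of sparse spiking that can persist for minutes. The unfiltered DC
#' channel additionally carries a negative sensillum-potential deflection
#' that is latency-locked to each stimulus.
#'
#' Tonic rate/duration and LLPR defaults are free parameters of the
#' simulator (chosen as plausible for moth trichoid sensilla, see the
#' methods vignette); they are not measurements.
#'
#' @param n_phasic spikes in the phasic burst (default 10).
#' @param f_phasic phasic instantaneous rate in Hz (default 150; ten spikes
#'   then span ~60 ms, inside the 100 ms phasic window).
#' @param phasic_shape gamma-renewal shape of phasic ISIs; large values give
#'   near-regular high-frequency spiking, `Inf` gives exactly regular ISIs.
#' @param tonic_rate,tonic_duration Poisson rate (Hz) and duration (s) of
#'   the tonic component.
#' @param pause_duration silent gap (s) between tonic component and LLPR.
#' @param llpr_rate,llpr_duration Poisson rate (Hz) and maximal duration (s)
#'   of the LLPR (always truncated at the next stimulus).
#' @param spa_true magnitude (mV) of the negative DC deflection.
#' @param latency_true first-spike latency (ms) relative to the start of the
#'   DC response.
#' @param dc_delay transduction delay (s) from valve opening to the start of
#'   the DC response.
#' @param drift named numeric vector of linear drifts per minute of
#'   recording time, applied to the generating parameters. Recognised
#'   names: `f6ap_hz` (drifts `f_phasic`), `latency_ms`, `spa_mv`,
#'   `tonic_rate`, `llpr_rate`.
#' @param spontaneous_rate background spiking rate (Hz).
#' @param noise_sd additive white Gaussian noise SD per channel (mV).
#' @param spike_amplitude peak amplitude (mV) of the biphasic spike
#'   waveform.
#' @param min_isi hard refractory interval (s) enforced on generated trains.
#' @return object of class `ground_truth_params`.
#' @export
ground_truth_params <- function(n_phasic = 10, f_phasic = 150,
                                phasic_shape = 50,
                                tonic_rate = 40, tonic_duration = 0.5,
                                pause_duration = 2,
                                llpr_rate = 1, llpr_duration = 600,
                                spa_true = 5, latency_true = 20,
                                dc_delay = 0.01,
                                drift = numeric(0),
                                spontaneous_rate = 0.2,
                                noise_sd = 0.05,
                                spike_amplitude = 1,
                                min_isi = 0.0015) {
  drift <- if (length(drift)) unlist(drift) else numeric(0) # accept lists
  gt <- list(n_phasic = n_phasic, f_phasic = f_phasic,
             phasic_shape = phasic_shape,
             tonic_rate = tonic_rate, tonic_duration = tonic_duration,
             pause_duration = pause_duration,
             llpr_rate = llpr_rate, llpr_duration = llpr_duration,
             spa_true = spa_true, latency_true = latency_true,
             dc_delay = dc_delay, drift = drift,
             spontaneous_rate = spontaneous_rate, noise_sd = noise_sd,
             spike_amplitude = spike_amplitude, min_isi = min_isi)
  with(gt, {
    stopifnot(n_phasic >= 0, f_phasic >= 0, tonic_rate >= 0,
              tonic_duration >= 0, pause_duration >= 0, llpr_rate >= 0,
              llpr_duration >= 0, spa_true >= 0, latency_true >= 0,
              spontaneous_rate >= 0, noise_sd >= 0, spike_amplitude > 0,
              min_isi >= 0)
  })
  bad <- setdiff(names(drift),
                 c("f6ap_hz", "latency_ms", "spa_mv", "tonic_rate",
                   "llpr_rate"))
  if (length(bad)) stop("unknown drift parameter(s): ",
                        paste(bad, collapse = ", "))
  structure(gt, class = "ground_truth_params")
}

#' Cohort design for synthetic recordings
#'
#' @param groups data.frame with columns `condition`, `zt`, `n_animals`
#'   (one row per experimental group).
#' @param stimulus_interval inter-stimulus interval in seconds (default
#'   300 s: one 50 ms pulse every 5 minutes avoids desensitisation).
#' @param stimulus_duration stimulus pulse length in seconds (default 0.05).
#' @param recording_duration recording length in minutes (default 120).
#' @param first_stimulus time (s) of the first stimulus; a positive value
#'   leaves a pre-stimulus baseline for onset detection.
#' @param paired if `TRUE`, each animal is recorded twice: a day-1 control
#'   recording with `n_stimuli_day1` stimulations and a day-2 treatment
#'   recording with `n_stimuli_day2` (the paired toxin protocol: three
#'   control stimulations, six treatment stimulations).
#' @param n_stimuli_day1,n_stimuli_day2 stimulus counts for paired designs.
#' @param sampling_rate Hz (default 20000).
#' @param early_window early spike-count window (s); 1.0 for unpaired
#'   pharmacology designs, 0.1 for paired toxin designs.
#' @param llpr_exclusion seconds after each stimulus excluded from the LLPR
#'   count (default 5).
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(groups = data.frame(condition = "control",
                                              zt = "ZT1-3", n_animals = 1),
                          stimulus_interval = 300,
                          stimulus_duration = 0.05,
                          recording_duration = 120,
                          first_stimulus = 0,
                          paired = FALSE,
                          n_stimuli_day1 = 3, n_stimuli_day2 = 6,
                          sampling_rate = 20000,
                          early_window = 1.0,
                          llpr_exclusion = 5) {
  stopifnot(is.data.frame(groups),
            all(c("condition", "zt", "n_animals") %in% names(groups)),
            all(groups$n_animals >= 1),
            stimulus_interval > stimulus_duration,
            recording_duration > 0, sampling_rate > 0,
            first_stimulus >= 0, early_window > 0, llpr_exclusion >= 0)
  structure(list(groups = groups,
                 stimulus_interval = stimulus_interval,
                 stimulus_duration = stimulus_duration,
                 recording_duration = recording_duration,
                 first_stimulus = first_stimulus,
                 paired = paired,
                 n_stimuli_day1 = n_stimuli_day1,
                 n_stimuli_day2 = n_stimuli_day2,
                 sampling_rate = sampling_rate,
                 early_window = early_window,
                 llpr_exclusion = llpr_exclusion),
            class = "cohort_design")
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# parameters after linear drift at recording time t (minutes); rates and
# magnitudes are clamped at zero and the clamp recorded
drifted_params <- function(gt, t_min) {
  d <- function(key, base) {
    v <- base + (gt$drift[key] %||na% 0) * t_min
    v
  }
  raw <- c(f_phasic = d("f6ap_hz", gt$f_phasic),
           latency_ms = d("latency_ms", gt$latency_true),
           spa_mv = d("spa_mv", gt$spa_true),
           tonic_rate = d("tonic_rate", gt$tonic_rate),
           llpr_rate = d("llpr_rate", gt$llpr_rate))
  clamped <- any(raw < 0)
  raw <- pmax(raw, 0)
  list(values = raw, clamped = clamped)
}

`%||na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else unname(a)

# spike times for one stimulation epoch, in seconds from recording start
simulate_stimulus_spikes <- function(gt, pv, stim_onset, next_onset) {
  resp_onset <- stim_onset + gt$dc_delay
  spikes <- numeric(0)
  p <- pv$values
  if (gt$n_phasic >= 1 && p[["f_phasic"]] > 0) {
    t1 <- resp_onset + p[["latency_ms"]] / 1000
    n_isi <- gt$n_phasic - 1
    isi <- if (n_isi == 0) numeric(0)
    else if (is.infinite(gt$phasic_shape)) rep(1 / p[["f_phasic"]], n_isi)
    else stats::rgamma(n_isi, shape = gt$phasic_shape,
                       rate = gt$phasic_shape * p[["f_phasic"]])
    spikes <- t1 + c(0, cumsum(isi))
  }
  tonic_start <- if (length(spikes)) max(spikes) else resp_onset
  spikes <- c(spikes,
              poisson_times(p[["tonic_rate"]], tonic_start,
                            tonic_start + gt$tonic_duration))
  llpr_start <- tonic_start + gt$tonic_duration + gt$pause_duration
  llpr_end <- min(llpr_start + gt$llpr_duration, next_onset)
  spikes <- c(spikes, poisson_times(p[["llpr_rate"]], llpr_start, llpr_end))
  list(resp_onset = resp_onset, spikes = spikes)
}

poisson_times <- function(rate, from, to) {
  if (rate <= 0 || to <= from) return(numeric(0))
  n <- stats::rpois(1, rate * (to - from))
  if (n == 0) return(numeric(0))
  sort(stats::runif(n, from, to))
}

thin_refractory <- function(times, min_isi) {
  times <- sort(times)
  if (length(times) < 2 || min_isi <= 0) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= min_isi) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

# true per-stimulus response parameters from the realized spike train
truth_row <- function(spikes, resp_onset, stim_onset, next_onset, pv,
                      early_window, llpr_exclusion, interval) {
  post <- spikes[spikes >= resp_onset & spikes < resp_onset + 1]
  latency <- if (length(post)) (post[1] - resp_onset) * 1000 else NA_real_
  f6 <- if (length(post) >= 6) mean(1 / diff(post[1:6])) else NA_real_
  # LLPR truth only when the full inter-stimulus window fits the recording
  llpr_end <- stim_onset + interval
  data.frame(
    stimulation_time_min = stim_onset / 60,
    response_onset_s = resp_onset,
    latency_ms = latency,
    f6ap_hz = f6,
    spa_mv = pv$values[["spa_mv"]],
    n_aps_early = sum(spikes >= resp_onset &
                        spikes < resp_onset + early_window),
    n_aps_llpr = if (next_onset >= llpr_end - 1e-9 &&
                       llpr_end > stim_onset + llpr_exclusion)
      sum(spikes >= stim_onset + llpr_exclusion & spikes < llpr_end)
    else NA_integer_,
    clamped = pv$clamped
  )
}

# biphasic extracellular spike template over ~2 ms: dominant positive lobe
# followed by a smaller repolarisation lobe (the asymmetry fixes the
# detection polarity); the positive peak defines the spike time
spike_template <- function(sampling_rate, amplitude, width = 0.002) {
  n <- max(4L, round(width * sampling_rate))
  tt <- seq_len(n) / n
  w <- sin(2 * pi * tt) * (1 - 0.5 * tt)
  w <- w / max(w) * amplitude
  list(w = w, peak = which.max(w))
}

# DC deflection kernel: fast (but C1-smooth) drop, slow recovery,
# normalised to peak 1. The squared soft-start term keeps the onset corner
# out of the 150 Hz AC passband so the deflection does not masquerade as a
# spike on a derived AC channel, while staying monotone near the onset.
dc_kernel <- function(sampling_rate, tau_on = 0.01, tau_slow = 0.5,
                      length_s = 6 * 0.5) {
  t <- seq(0, length_s, by = 1 / sampling_rate)
  h <- (1 - exp(-t / tau_on))^2 * exp(-t / tau_slow)
  h / max(h)
}

add_at <- function(x, start_idx, w) {
  i0 <- max(1L, start_idx)
  i1 <- min(length(x), start_idx + length(w) - 1L)
  if (i1 < i0) return(x)
  x[i0:i1] <- x[i0:i1] + w[(i0 - start_idx + 1L):(i1 - start_idx + 1L)]
  x
}

render_channels <- function(spike_samples, dc_events, n_samples,
                            sampling_rate, gt) {
  tpl <- spike_template(sampling_rate, gt$spike_amplitude)
  spikes_tr <- numeric(n_samples)
  for (s in spike_samples) {
    spikes_tr <- add_at(spikes_tr, s - tpl$peak + 1L, tpl$w)
  }
  defl <- numeric(n_samples)
  if (nrow(dc_events)) {
    ker <- dc_kernel(sampling_rate)
    for (i in seq_len(nrow(dc_events))) {
      defl <- add_at(defl, dc_events$sample[i], -dc_events$spa[i] * ker)
    }
  }
  dc <- defl + spikes_tr
  ac <- spikes_tr
  if (gt$noise_sd > 0) {
    dc <- dc + stats::rnorm(n_samples, sd = gt$noise_sd)
    ac <- ac + stats::rnorm(n_samples, sd = gt$noise_sd)
  }
  list(dc = dc, ac = ac)
}

#' Generate one synthetic tip-recording with known ground truth
#'
#' Simulates the scheduled stimulations of `design` for a single animal,
#' realises the three-component spike response and DC deflection for each
#' stimulus (with any per-minute parameter drift), and optionally renders
#' the spike train into dual-channel traces. Identical `(gt, design, seed)`
#' give bit-identical output. Spike times are quantised to the sample grid
#' so that rendered traces and the ground-truth table agree exactly.
#'
#' @param gt a [ground_truth_params()] object.
#' @param design a [cohort_design()] (its group table is ignored here).
#' @param seed integer seed.
#' @param render `"trace"` renders full-length dc/ac traces (memory scales
#'   with duration x sampling rate), `"epochs"` renders one short trace per
#'   stimulus (window `[-epoch_pre, +epoch_post]` around the valve
#'   opening), `"none"` returns only spike times and the truth table.
#' @param epoch_pre,epoch_post epoch window (s) for `render = "epochs"`.
#' @param meta metadata list stored in the rendered recording(s).
#' @param stimulus_onsets optional explicit onset times (s); defaults to
#'   the periodic schedule of `design`.
#' @return list with `truth` (per-stimulus ground-truth feature table),
#'   `spike_times` (s), and depending on `render` either `recording` (an
#'   [ssr_recording()]) or `epochs` (list of single-stimulus recordings).
#' @export
generate_recording <- function(gt, design = cohort_design(), seed = 1,
                               render = c("trace", "epochs", "none"),
                               epoch_pre = 1.0, epoch_post = 1.5,
                               meta = list(), stimulus_onsets = NULL) {
  stopifnot(inherits(gt, "ground_truth_params"),
            inherits(design, "cohort_design"))
  render <- match.arg(render)
  fs <- design$sampling_rate
  dur_s <- design$recording_duration * 60
  onsets <- stimulus_onsets %||%
    seq(design$first_stimulus, dur_s - 1e-6, by = design$stimulus_interval)
  if (!length(onsets)) stop("design schedules no stimulus onsets")
  with_seed(seed, {
    all_spikes <- poisson_times(gt$spontaneous_rate, 0, dur_s)
    truth <- vector("list", length(onsets))
    dc_events <- data.frame(sample = integer(0), spa = numeric(0))
    next_onsets <- c(onsets[-1], dur_s)
    for (i in seq_along(onsets)) {
      pv <- drifted_params(gt, onsets[i] / 60)
      sim <- simulate_stimulus_spikes(gt, pv, onsets[i], next_onsets[i])
      all_spikes <- c(all_spikes, sim$spikes)
      dc_events <- rbind(dc_events,
                         data.frame(sample = round(sim$resp_onset * fs) + 1L,
                                    spa = pv$values[["spa_mv"]]))
      truth[[i]] <- list(resp_onset = sim$resp_onset, pv = pv)
    }
    # quantise to the sample grid, then enforce the refractory interval
    all_spikes <- round(sort(all_spikes) * fs) / fs
    all_spikes <- thin_refractory(all_spikes, gt$min_isi)
    all_spikes <- all_spikes[all_spikes >= 0 & all_spikes < dur_s]
    truth_df <- do.call(rbind, lapply(seq_along(onsets), function(i) {
      truth_row(all_spikes, truth[[i]]$resp_onset, onsets[i],
                next_onsets[i], truth[[i]]$pv,
                design$early_window, design$llpr_exclusion,
                design$stimulus_interval)
    }))
    out <- list(truth = truth_df, spike_times = all_spikes,
                stimulus_onsets = onsets)
    if (render == "trace") {
      n_samples <- round(dur_s * fs)
      ch <- render_channels(round(all_spikes * fs) + 1L, dc_events,
                            n_samples, fs, gt)
      out$recording <- ssr_recording(
        dc = ch$dc, ac = ch$ac, sampling_rate = fs,
        stimulus_onsets = onsets,
        meta = utils::modifyList(
          list(stimulus_duration = design$stimulus_duration), meta))
    } else if (render == "epochs") {
      out$epochs <- lapply(seq_along(onsets), function(i) {
        t0 <- onsets[i] - epoch_pre
        n_samples <- round((epoch_pre + epoch_post) * fs)
        in_win <- all_spikes >= t0 & all_spikes < t0 + epoch_pre + epoch_post
        ev_samp <- dc_events$sample[i] - round(t0 * fs)
        ch <- render_channels(round((all_spikes[in_win] - t0) * fs) + 1L,
                              data.frame(sample = ev_samp,
                                         spa = dc_events$spa[i]),
                              n_samples, fs, gt)
        ssr_recording(dc = ch$dc, ac = ch$ac, sampling_rate = fs,
                      stimulus_onsets = epoch_pre,
                      meta = utils::modifyList(
                        list(stimulus_duration = design$stimulus_duration,
                             epoch_time_min = onsets[i] / 60), meta))
      })
    }
    out
  })
}

#' Generate a synthetic cohort with group structure
#'
#' One recording per animal (two per animal for paired toxin designs:
#' day-1 control with three stimulations, day-2 treatment with six),
#' with group labels propagated into the metadata and truth tables and
#' per-animal seeds derived deterministically from `seed`.
#'
#' @param design a [cohort_design()]; its `groups` table defines the
#'   condition x zeitgeber-time cells and animal counts.
#' @param gt_by_group named list of [ground_truth_params()], one entry per
#'   condition label (plus a `"control"` entry for paired designs).
#' @param seed integer master seed.
#' @param render passed to [generate_recording()] (`"none"` keeps only
#'   spike times and truth tables, which is what the statistical
#'   calibrations need).
#' @return list with `truth` (row-bound per-stimulus truth table with
#'   `animal_id`, `condition`, `zt`, `day` columns) and `animals` (per
#'   animal/day: the [generate_recording()] output).
#' @export
generate_cohort <- function(design, gt_by_group, seed = 1,
                            render = c("none", "trace", "epochs")) {
  stopifnot(inherits(design, "cohort_design"))
  render <- match.arg(render)
  need <- unique(as.character(design$groups$condition))
  if (design$paired) need <- union(need, "control")
  missing_g <- setdiff(need, names(gt_by_group))
  if (length(missing_g)) {
    stop("no ground-truth parameters for group(s): ",
         paste(missing_g, collapse = ", "))
  }
  n_total <- sum(design$groups$n_animals)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, 2 * n_total))
  animals <- list()
  truth <- list()
  idx <- 0L
  for (g in seq_len(nrow(design$groups))) {
    cond <- as.character(design$groups$condition[g])
    zt <- as.character(design$groups$zt[g])
    for (a in seq_len(design$groups$n_animals[g])) {
      idx <- idx + 1L
      aid <- sprintf("%s_%s_a%02d", cond, zt, a)
      if (design$paired) {
        d1 <- periodic_design(design, design$n_stimuli_day1)
        d2 <- periodic_design(design, design$n_stimuli_day2)
        r1 <- generate_recording(gt_by_group[["control"]], d1,
                                 seed = seeds[2 * idx - 1], render = render,
                                 meta = list(animal_id = aid,
                                             condition = cond, zt_window = zt,
                                             day = 1))
        r2 <- generate_recording(gt_by_group[[cond]], d2,
                                 seed = seeds[2 * idx], render = render,
                                 meta = list(animal_id = aid,
                                             condition = cond, zt_window = zt,
                                             day = 2))
        animals[[paste0(aid, "_d1")]] <- r1
        animals[[paste0(aid, "_d2")]] <- r2
        truth[[paste0(aid, "_d1")]] <-
          cbind(animal_id = aid, condition = "control", zt = zt, day = 1,
                r1$truth)
        truth[[paste0(aid, "_d2")]] <-
          cbind(animal_id = aid, condition = cond, zt = zt, day = 2,
                r2$truth)
      } else {
        r <- generate_recording(gt_by_group[[cond]], design,
                                seed = seeds[2 * idx - 1], render = render,
                                meta = list(animal_id = aid,
                                            condition = cond, zt_window = zt,
                                            day = 1))
        animals[[aid]] <- r
        truth[[aid]] <- cbind(animal_id = aid, condition = cond, zt = zt,
                              day = 1, r$truth)
      }
    }
  }
  list(truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       animals = animals)
}

periodic_design <- function(design, n_stimuli) {
  d <- design
  d$recording_duration <-
    (design$first_stimulus + n_stimuli * design$stimulus_interval) / 60
  d
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Emulates the tissue-collection design of three biological samples per
#' zeitgeber time with three technical qPCR replicates each. Target-gene Ct
#' values are shifted by `-log2(fold)` relative to the calibrator ZT;
#' reference genes are generated with fold change 1 at every ZT.
#'
#' @param genes character vector of target genes.
#' @param zts character vector of zeitgeber-time labels.
#' @param fold_changes named list: per target gene, a named numeric vector
#'   of fold changes by ZT (missing entries default to 1). All folds > 0.
#' @param sigma_ct SD (cycles) of technical measurement noise, >= 0.
#' @param seed integer seed.
#' @param n_bio,n_tech biological / technical replicates (defaults 3 and 3).
#' @param base_ct baseline target Ct (cycles).
#' @param references named numeric vector of reference genes and their
#'   baseline Cts (defaults `RPS13` = 18, `G3PDH` = 21).
#' @param sigma_bio SD (cycles) of a shared per-biological-replicate offset
#'   (applied to all genes alike, so it cancels in ddCt; default 0).
#' @return data.frame with columns `gene`, `zt`, `biological_replicate`,
#'   `technical_replicate`, `ct`.
#' @export
generate_qpcr_dataset <- function(genes, zts = c("ZT1", "ZT9", "ZT17"),
                                  fold_changes = list(), sigma_ct = 0.2,
                                  seed = 1, n_bio = 3, n_tech = 3,
                                  base_ct = 25,
                                  references = c(RPS13 = 18, G3PDH = 21),
                                  sigma_bio = 0) {
  stopifnot(sigma_ct >= 0, sigma_bio >= 0, n_bio >= 1, n_tech >= 1)
  for (g in names(fold_changes)) {
    if (any(fold_changes[[g]] <= 0)) {
      stop("fold changes must be positive (gene ", g, ")")
    }
  }
  with_seed(seed, {
    rows <- list()
    for (z in zts) {
      for (b in seq_len(n_bio)) {
        bio_off <- if (sigma_bio > 0) stats::rnorm(1, sd = sigma_bio) else 0
        for (g in genes) {
          fold <- 1
          fc <- fold_changes[[g]]
          if (!is.null(fc) && z %in% names(fc)) fold <- fc[[z]]
          mu <- base_ct - log2(fold) + bio_off
          ct <- mu + if (sigma_ct > 0) stats::rnorm(n_tech, sd = sigma_ct)
          else rep(0, n_tech)
          rows[[length(rows) + 1]] <- data.frame(
            gene = g, zt = z, biological_replicate = b,
            technical_replicate = seq_len(n_tech), ct = ct)
        }
        for (rg in names(references)) {
          mu <- references[[rg]] + bio_off
          ct <- mu + if (sigma_ct > 0) stats::rnorm(n_tech, sd = sigma_ct)
          else rep(0, n_tech)
          rows[[length(rows) + 1]] <- data.frame(
            gene = rg, zt = z, biological_replicate = b,
            technical_replicate = seq_len(n_tech), ct = ct)
        }
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
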
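#' Build the cumulative peri-stimulus time histogram
#'
#' Spikes of the first second after each response onset are counted in
#' 10 ms bins and summed across all stimulations of one animal; the
#' cumulative (prefix) sum of this pooled histogram is the fit target for
#' [fit_response_sigmoid()].
#'
#' @param spike_trains list of spike-time vectors (s), one per stimulation
#'   (a `spike_train` object is also accepted per element).
#' @param onsets numeric vector of response-onset times (s), aligned 1:1
#'   with `spike_trains`.
#' @param bin_width bin width in seconds (default 0.01); must divide
#'   `horizon` to within rounding.
#' @param horizon analysis horizon in seconds after onset (default 1).
#' @return object of class `cumulative_psth`: list with `bin_edges`
#'   (length bins + 1), `counts`, `cumulative`, `n_stimulations`.
#' @export
build_cumulative_psth <- function(spike_trains, onsets, bin_width = 0.01,
                                  horizon = 1.0) {
  if (length(spike_trains) != length(onsets)) {
    stop("spike_trains and onsets must be aligned 1:1")
  }
  stopifnot(bin_width > 0, horizon > 0)
  nbins <- horizon / bin_width
  if (abs(nbins - round(nbins)) > 1e-9) {
    stop("bin_width must divide horizon")
  }
  nbins <- as.integer(round(nbins))
  counts <- integer(nbins)
  for (i in seq_along(spike_trains)) {
    st <- spike_trains[[i]]
    if (inherits(st, "spike_train")) st <- st$spike_times
    rel <- st - onsets[i]
    rel <- rel[rel >= 0 & rel < horizon]
    if (length(rel)) {
      idx <- pmin(nbins, floor(rel / bin_width) + 1L)
      counts <- counts + tabulate(idx, nbins)
    }
  }
  structure(list(bin_edges = seq(0, horizon, by = bin_width),
                 counts = counts,
                 cumulative = cumsum(counts),
                 n_stimulations = length(spike_trains)),
            class = "cumulative_psth")
}

#' @export
print.cumulative_psth <- function(x, ...) {
  cat(sprintf("<cumulative_psth> %d bins x %g s, %d stimulations, %d spikes\n",
              length(x$counts), diff(x$bin_edges[1:2]), x$n_stimulations,
              x$cumulative[length(x$cumulative)]))
  invisible(x)
}

sigmoid_model <- function(t, ap_max, t_half, k) {
  z <- (t - t_half) / k
  z <- pmin(pmax(z, -700), 700)
  ap_max / (1 + exp(z))
}

#' Fit the response-kinetics sigmoid to a cumulative PSTH
#'
#' Nonlinear least squares of `AP(t) = AP_max / (1 + exp((t - t_half)/k))`
#' to the cumulative histogram evaluated at bin centers. As printed, the
#' curve is increasing only for `k < 0`, so `k` is constrained negative;
#' every accepted fit is therefore monotone non-decreasing. A steeper
#' response has `k` closer to zero; summaries of slope magnitude should use
#' `abs(k)` (and group statistics on slope use `log10(abs(k))`).
#'
#' Initialisation is deterministic: `ap_max` starts at the final cumulative
#' count, `t_half` at the first bin center where the cumulative reaches
#' half of it, and `k` at `-(t75 - t25)/2.2` from the quartile-crossing
#' times, so identical inputs give identical fits.
#'
#' @param cp a [build_cumulative_psth()] object.
#' @return object of class `sigmoid_fit`: list with `ap_max`, `t_half`,
#'   `k` (s, negative), `rss`, `converged`, `n_stimulations`, and
#'   `diagnostics` (optimizer message).
#' @export
fit_response_sigmoid <- function(cp) {
  stopifnot(inherits(cp, "cumulative_psth"))
  y <- cp$cumulative
  if (y[length(y)] <= 0) {
    stop("cumulative PSTH contains no spikes; nothing to fit")
  }
  bw <- diff(cp$bin_edges[1:2])
  t <- cp$bin_edges[-length(cp$bin_edges)] + bw / 2
  ap0 <- y[length(y)]
  t50 <- t[which(y >= ap0 / 2)[1]]
  t25 <- t[which(y >= ap0 / 4)[1]]
  t75 <- t[which(y >= 3 * ap0 / 4)[1]]
  k0 <- -(t75 - t25) / 2.2
  if (!is.finite(k0) || k0 >= 0) k0 <- -bw / 4
  start <- c(ap_max = ap0, t_half = t50, k = k0)
  lower <- c(1e-9, 0, -10 * max(t))
  upper <- c(Inf, max(t) * 10, -1e-9)
  fit <- tryCatch({
    m <- stats::nls(y ~ sigmoid_model(t, ap_max, t_half, k),
                    data = list(y = y, t = t),
                    start = as.list(start),
                    algorithm = "port", lower = lower, upper = upper,
                    control = stats::nls.control(maxiter = 1000,
                                                 tol = 1e-12,
                                                 minFactor = 1e-12,
                                                 warnOnly = TRUE))
    cf <- stats::coef(m)
    list(par = cf, rss = sum(stats::resid(m)^2),
         converged = m$convInfo$isConv %||% TRUE,
         msg = m$convInfo$stopMessage %||% "converged")
  }, error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to bounded quasi-Newton on the residual sum of squares
    obj <- function(p) {
      r <- y - sigmoid_model(t, p[1], p[2], p[3])
      sum(r * r)
    }
    o <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 2000, factr = 1e3))
    fit <- list(par = o$par, rss = o$value,
                converged = o$convergence == 0,
                msg = paste("L-BFGS-B:", o$convergence,
                            o$message %||% ""))
  }
  structure(list(ap_max = unname(fit$par[1]),
                 t_half = unname(fit$par[2]),
                 k = unname(fit$par[3]),
                 rss = fit$rss,
                 converged = isTRUE(fit$converged),
                 n_stimulations = cp$n_stimulations,
                 diagnostics = fit$msg),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(paste0("<sigmoid_fit> AP_max = %.2f, t_1/2 = %.4f s, ",
                     "k = %.5f s (rss %.3g, %s)\n"),
              x$ap_max, x$t_half, x$k, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predict from a fitted response sigmoid
#'
#' @param object a `sigmoid_fit`.
#' @param t times (s) at which to evaluate the fitted curve.
#' @param ... ignored.
#' @return numeric vector of fitted cumulative spike counts.
#' @export
predict.sigmoid_fit <- function(object, t, ...) {
  sigmoid_model(t, object$ap_max, object$t_half, object$k)
}

#' Per-animal response-kinetics fits for a recording
#'
#' Convenience wrapper: detects spikes and response onsets on a recording,
#' pools all stimulations into the cumulative 10 ms PSTH of the first
#' second, and fits the kinetics sigmoid.
#'
#' @param rec an [ssr_recording()].
#' @param bin_width,horizon passed to [build_cumulative_psth()].
#' @param ... passed to [detect_response_onset()].
#' @return a `sigmoid_fit` with the `cumulative_psth` attached as
#'   attribute `"psth"`.
#' @export
fit_recording_kinetics <- function(rec, bin_width = 0.01, horizon = 1.0,
                                   ...) {
  stopifnot(inherits(rec, "ssr_recording"))
  fs <- rec$sampling_rate
  spk <- detect_spikes(rec$ac, fs)
  onsets <- vapply(rec$stimulus_onsets, function(so) {
    tryCatch(detect_response_onset(rec$dc, so, fs, ...),
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- !is.na(onsets)
  cp <- build_cumulative_psth(rep(list(spk$spike_times), sum(ok)),
                              onsets[ok], bin_width, horizon)
  ft <- fit_response_sigmoid(cp)
  attr(ft, "psth") <- cp
  ft
}
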
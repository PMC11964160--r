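# Independent oracle implementations used to cross-check the package's
# statistics. They deliberately use different code paths than the package
# (base-R model fits where the package computes sums of squares by hand,
# textbook formulas where the package calls a stats:: routine).

# OLS slope + two-sided t test, closed form
oracle_slope <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(x)
  rss <- sum((y - alpha - beta * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tt <- beta / se
  list(slope = beta, intercept = alpha,
       p = 2 * stats::pt(-abs(tt), n - 2))
}

# one-way ANOVA F via base-R lm/anova (package computes SS directly)
oracle_anova_f <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  av <- anova(lm(y ~ g))
  list(f = av$`F value`[1], p = av$`Pr(>F)`[1],
       df_between = av$Df[1], df_residual = av$Df[2])
}

# Kruskal-Wallis H by the textbook rank-sum formula with tie correction
# (package calls stats::kruskal.test)
oracle_kw_h <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(y)
  r <- rank(y)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
  ties <- table(y)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# one-way repeated-measures ANOVA by explicit sum-of-squares decomposition
# for a complete balanced animal x condition matrix (package uses lm())
oracle_rm_f <- function(m) { # matrix: rows = animals, cols = conditions
  a <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_cond <- a * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  f <- (ss_cond / (k - 1)) / (ss_err / ((a - 1) * (k - 1)))
  list(f = f, df_between = k - 1, df_residual = (a - 1) * (k - 1),
       p = stats::pf(f, k - 1, (a - 1) * (k - 1), lower.tail = FALSE))
}

# exhaustive local-extrema scan above a threshold (oracle for the spike
# detector): every sample that is a strict local maximum above threshold,
# then greedy refractory pruning
oracle_detect <- function(x, fs, threshold, refractory = 0.001) {
  idx <- which(x >= threshold)
  idx <- idx[idx > 1 & idx < length(x)]
  peaks <- idx[x[idx] >= x[idx - 1] & x[idx] >= x[idx + 1]]
  times <- (peaks - 1) / fs
  keep <- numeric(0)
  for (t in times) {
    if (!length(keep) || t - keep[length(keep)] >= refractory) {
      keep <- c(keep, t)
    } else if (x[round(t * fs) + 1] > x[round(keep[length(keep)] * fs) + 1]) {
      # same excursion: keep the larger extremum
      keep[length(keep)] <- t
    }
  }
  keep
}

# build a trace with spike templates at given times (for detector tests)
make_spike_trace <- function(times, fs = 20000, dur = 0.5, amp = 1,
                             noise_sd = 0) {
  n <- round(dur * fs)
  x <- numeric(n)
  tpl <- ssrquant:::spike_template(fs, amp)
  for (t in times) {
    x <- ssrquant:::add_at(x, round(t * fs) + 1L - tpl$peak + 1L, tpl$w)
  }
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  x
}

# F1 of detected vs true spike times with a matching tolerance
f1_score <- function(truth, detected, tol = 5e-4) {
  tp <- sum(vapply(truth, function(t) any(abs(detected - t) <= tol),
                   logical(1)))
  2 * tp / (length(truth) + length(detected))
}

# cumulative_psth straight from a cumulative vector (for fit tests)
cp_from_cumulative <- function(y, bin_width = 0.01) {
  structure(list(bin_edges = seq(0, length(y) * bin_width, by = bin_width),
                 counts = diff(c(0, y)), cumulative = y,
                 n_stimulations = 1L),
            class = "cumulative_psth")
}

short_design <- function(n_stim = 3, interval = 15, fs = 20000, ...) {
  cohort_design(stimulus_interval = interval,
                recording_duration = (1 + n_stim * interval) / 60,
                first_stimulus = 1, sampling_rate = fs, ...)
}
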
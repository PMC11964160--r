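#' Per-animal linear slope of a response parameter with significance gating
#'
#' Drug effects build up slowly during long tip-recordings, so each
#' response parameter is summarised per animal as the slope of an ordinary
#' least-squares line over recording time. Slopes whose two-sided t test
#' against zero is not significant are set to exactly zero
#' (`gated_slope`), i.e. "no significant change of the response over
#' time"; only gated slopes enter the group comparisons. An exact
#' zero-residual line is treated as significant (the t statistic diverges).
#'
#' @param times stimulation times in minutes.
#' @param values parameter values (same length); `NA` pairs are dropped.
#' @param alpha significance level of the gate (default 0.05).
#' @param parameter optional parameter name carried into the record.
#' @param experiment_id optional id carried into the record.
#' @return one-row data.frame (`slope_record`): `experiment_id`,
#'   `parameter`, `slope` (units/min), `intercept`, `p_slope`,
#'   `gated_slope`, `n_points`.
#' @export
fit_parameter_slope <- function(times, values, alpha = 0.05,
                                parameter = NA_character_,
                                experiment_id = NA_character_) {
  stopifnot(length(times) == length(values))
  ok <- !is.na(times) & !is.na(values)
  x <- times[ok]
  y <- values[ok]
  n <- length(x)
  if (n < 3) {
    return(data.frame(experiment_id = experiment_id, parameter = parameter,
                      slope = NA_real_, intercept = NA_real_,
                      p_slope = NA_real_, gated_slope = 0, n_points = n))
  }
  if (stats::var(x) == 0) {
    stop("zero variance in stimulation times; slope undefined")
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  # zero-residual fits warn in summary(); the divergent t is handled below
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) >= 2) sm["x", "Pr(>|t|)"] else NA_real_
  # zero residual variance: t diverges, slope is (limiting-case) significant
  if (!is.finite(p)) {
    p <- if (sum(stats::resid(fit)^2) < 1e-20 * max(1, sum(y^2))) 0 else NA
  }
  gated <- if (!is.na(p) && p < alpha) unname(cf[2]) else 0
  data.frame(experiment_id = experiment_id, parameter = parameter,
             slope = unname(cf[2]), intercept = unname(cf[1]),
             p_slope = p, gated_slope = gated, n_points = n)
}

#' Gated slopes for every animal and parameter of a feature table
#'
#' @param ft long feature table (as from [extract_features()] or the truth
#'   table of [generate_cohort()]), with `experiment_id` or `animal_id`,
#'   `stimulation_time_min` and feature columns.
#' @param parameters feature columns to fit (default: all present).
#' @param alpha gate significance level.
#' @return data.frame of slope records, one row per animal x parameter,
#'   with any `condition`/`zt` labels carried along.
#' @export
fit_all_slopes <- function(ft, parameters = NULL, alpha = 0.05) {
  idcol <- if ("experiment_id" %in% names(ft)) "experiment_id" else "animal_id"
  stopifnot(idcol %in% names(ft), "stimulation_time_min" %in% names(ft))
  parameters <- parameters %||% intersect(FEATURE_COLS, names(ft))
  out <- list()
  for (id in unique(ft[[idcol]])) {
    sub <- ft[ft[[idcol]] == id, ]
    for (p in parameters) {
      rec <- fit_parameter_slope(sub$stimulation_time_min, sub[[p]],
                                 alpha = alpha, parameter = p,
                                 experiment_id = id)
      for (lab in intersect(c("condition", "zt"), names(sub))) {
        rec[[lab]] <- sub[[lab]][1]
      }
      out[[length(out) + 1]] <- rec
    }
  }
  do.call(rbind, out)
}

shapiro_pass <- function(x, alpha) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(unique(x)) < 2) return(TRUE) # cannot reject
  tryCatch(stats::shapiro.test(x)$p.value >= alpha,
           error = function(e) TRUE)
}

# Brown-Forsythe variant of Levene's test (median-centered), the robust
# default; returns TRUE when equal variance cannot be rejected
levene_pass <- function(groups, alpha) {
  z <- lapply(groups, function(g) abs(g - stats::median(g, na.rm = TRUE)))
  if (all(unlist(z) == 0)) return(TRUE)
  f <- oneway_anova_stats(z)
  is.na(f$p) || f$p >= alpha
}

# one-way fixed-effects ANOVA by direct sums of squares; handles the
# degenerate all-equal case as F = 0, p = 1
oneway_anova_stats <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  gmean <- mean(y)
  n <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gmean)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfr <- sum(n) - length(groups)
  eps <- 1e-12 * max(ssb + ssw, 1e-300) # relative floor for degenerate data
  if (ssb <= eps) {
    return(list(f = 0, p = 1, df_between = dfb, df_residual = dfr))
  }
  if (ssw <= eps) {
    return(list(f = Inf, p = 0, df_between = dfb, df_residual = dfr))
  }
  f <- (ssb / dfb) / (ssw / dfr)
  list(f = f, p = stats::pf(f, dfb, dfr, lower.tail = FALSE),
       df_between = dfb, df_residual = dfr)
}

tukey_posthoc <- function(groups) {
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  y <- unlist(groups, use.names = FALSE)
  fit <- stats::aov(y ~ g)
  tk <- stats::TukeyHSD(fit)$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], method = "Tukey",
             row.names = NULL)
}

# Dunn's z test on rank sums with tie correction; Bonferroni adjustment
dunn_posthoc <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  r <- rank(y)
  n <- length(y)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  labs <- names(groups)
  out <- list()
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      a <- labs[i]; b <- labs[j]
      se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[[a]] + 1 / ni[[b]]))
      z <- (rbar[[a]] - rbar[[b]]) / se
      out[[length(out) + 1]] <- data.frame(
        comparison = paste(b, a, sep = "-"), diff = rbar[[b]] - rbar[[a]],
        p_adj = min(1, 2 * stats::pnorm(-abs(z)) *
                      choose(length(labs), 2)),
        method = "Dunn")
    }
  }
  do.call(rbind, out)
}

#' Compare groups with the normality/variance decision tree
#'
#' The test-selection rule used throughout the pipeline: every group is
#' checked with the Shapiro-Wilk test and the groups jointly with a
#' median-centered Levene (Brown-Forsythe) test. If both pass, a one-way
#' ANOVA with Tukey post hoc is reported. If either fails and all values
#' are positive, the data are log-transformed and retested; if the
#' transformed data pass, the ANOVA runs on the log scale. Otherwise an
#' ANOVA on ranks (Kruskal-Wallis, statistic `H`) with Dunn's post hoc
#' test (Bonferroni-adjusted) is reported. Exactly one branch is taken.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values), or a data.frame with `value` and `group` columns.
#' @param alpha significance level for the assumption checks.
#' @param transform_policy `"auto"` (try log when assumptions fail) or
#'   `"none"` (go straight to ranks).
#' @return object of class `group_test`: list with `test`, `transform`,
#'   `statistic` (F or H), `df_between`, `df_residual` (parametric branch
#'   only), `p`, `normality_pass`, `variance_pass`, `posthoc` table.
#' @export
run_group_comparison <- function(groups, alpha = 0.05,
                                 transform_policy = c("auto", "none")) {
  transform_policy <- match.arg(transform_policy)
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs at least two values")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  norm_ok <- all(vapply(groups, shapiro_pass, logical(1), alpha = alpha))
  var_ok <- levene_pass(groups, alpha)
  transform <- "none"
  use <- groups
  if (!(norm_ok && var_ok) && transform_policy == "auto" &&
        all(unlist(groups) > 0)) {
    lg <- lapply(groups, log)
    if (all(vapply(lg, shapiro_pass, logical(1), alpha = alpha)) &&
          levene_pass(lg, alpha)) {
      use <- lg
      transform <- "log"
    }
  }
  parametric <- (norm_ok && var_ok) || transform == "log"
  if (parametric) {
    st <- oneway_anova_stats(use)
    posthoc <- tryCatch(tukey_posthoc(use), error = function(e) NULL)
    res <- list(test = "one-way ANOVA", transform = transform,
                statistic = st$f, df_between = st$df_between,
                df_residual = st$df_residual, p = st$p)
  } else {
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
    kw <- stats::kruskal.test(y, g)
    posthoc <- dunn_posthoc(groups)
    res <- list(test = "ANOVA on ranks (Kruskal-Wallis)",
                transform = "none",
                statistic = unname(kw$statistic),
                df_between = unname(kw$parameter), df_residual = NA,
                p = kw$p.value)
  }
  structure(c(res, list(normality_pass = norm_ok, variance_pass = var_ok,
                        posthoc = posthoc, n = vapply(groups, length,
                                                      integer(1)))),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  stat_lab <- if (grepl("rank", x$test)) "H" else "F"
  cat(sprintf("<group_test> %s%s: %s = %.3f, df = %s%s, p = %.4g\n",
              x$test,
              if (x$transform != "none") paste0(" [", x$transform, "]") else "",
              stat_lab, x$statistic, x$df_between,
              if (!is.na(x$df_residual))
                paste0(", res. ", x$df_residual) else "",
              x$p))
  invisible(x)
}

#' One-way repeated-measures ANOVA for paired designs
#'
#' Each animal serves as its own control (condition values are typically
#' per-animal means over that recording's stimulations). The omnibus test
#' removes the between-animal effect and tests the condition effect:
#' `value ~ animal + condition`, with the condition F on the residual
#' degrees of freedom. Animals contributing only one condition are
#' excluded with a message. Assumption checks (Shapiro-Wilk per condition,
#' Levene across conditions) are reported; if either fails and all values
#' are positive, the analysis is run on the log scale (mirroring the
#' "log-transformed to ensure equal variance" convention).
#'
#' @param data data.frame with columns `animal`, `condition`, `value`, or
#'   a named list of named vectors (`animal -> condition -> value`).
#' @param alpha assumption-check significance level.
#' @param transform_policy `"auto"` or `"none"`.
#' @return a `group_test` with `test = "RM ANOVA"` and a Tukey post hoc
#'   table based on the within-animal error term.
#' @export
run_rm_comparison <- function(data, alpha = 0.05,
                              transform_policy = c("auto", "none")) {
  transform_policy <- match.arg(transform_policy)
  if (!is.data.frame(data)) {
    data <- do.call(rbind, lapply(names(data), function(a) {
      data.frame(animal = a, condition = names(data[[a]]),
                 value = unname(unlist(data[[a]])))
    }))
  }
  stopifnot(all(c("animal", "condition", "value") %in% names(data)))
  data <- data[!is.na(data$value), ]
  tab <- table(unique(data[c("animal", "condition")])$animal)
  drop <- names(tab)[tab < 2]
  if (length(drop)) {
    message("excluding animal(s) with a single condition: ",
            paste(drop, collapse = ", "))
    data <- data[!data$animal %in% drop, ]
  }
  if (length(unique(data$condition)) < 2) {
    stop("need at least two conditions after exclusions")
  }
  conds <- split(data$value, data$condition)
  norm_ok <- all(vapply(conds, shapiro_pass, logical(1), alpha = alpha))
  var_ok <- levene_pass(conds, alpha)
  transform <- "none"
  if (!(norm_ok && var_ok) && transform_policy == "auto" &&
        all(data$value > 0)) {
    lg <- lapply(conds, log)
    if (all(vapply(lg, shapiro_pass, logical(1), alpha = alpha)) &&
          levene_pass(lg, alpha)) {
      data$value <- log(data$value)
      transform <- "log"
    }
  }
  an <- factor(data$animal)
  cond <- factor(data$condition)
  fit <- stats::lm(value ~ an + cond, data = data)
  av <- suppressWarnings(stats::anova(fit))
  frow <- av["cond", ]
  ssc <- frow$`Sum Sq`
  sse <- av["Residuals", "Sum Sq"]
  dfr <- av["Residuals", "Df"]
  eps <- 1e-12 * max(sum(av$`Sum Sq`), 1e-300)
  stat <- if (ssc <= eps) 0
  else if (sse <= eps) Inf
  else frow$`F value`
  p <- if (ssc <= eps) 1 else if (sse <= eps) 0 else frow$`Pr(>F)`
  mse <- sse / dfr
  # Tukey-Kramer on condition means against the within-animal error term
  means <- tapply(data$value, cond, mean)
  ni <- tapply(data$value, cond, length)
  labs <- levels(cond)
  posthoc <- list()
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      a <- labs[i]; b <- labs[j]
      se <- sqrt(mse / 2 * (1 / ni[[a]] + 1 / ni[[b]]))
      q <- abs(means[[b]] - means[[a]]) / se
      posthoc[[length(posthoc) + 1]] <- data.frame(
        comparison = paste(b, a, sep = "-"),
        diff = means[[b]] - means[[a]],
        p_adj = if (mse <= 1e-300) as.numeric(q > 0) * 0
        else stats::ptukey(q, length(labs), dfr, lower.tail = FALSE),
        method = "Tukey")
    }
  }
  structure(list(test = "RM ANOVA", transform = transform,
                 statistic = unname(stat),
                 df_between = frow$Df, df_residual = dfr, p = unname(p),
                 normality_pass = norm_ok, variance_pass = var_ok,
                 posthoc = do.call(rbind, posthoc),
                 n = length(levels(an))),
            class = "group_test")
}

#' Slope-based group comparison for every response parameter
#'
#' The full drug-effect analysis: per-animal gated slopes (via
#' [fit_all_slopes()]) compared across `condition x zt` groups with
#' [run_group_comparison()], one row of results per parameter - the layout
#' of the published slope-statistics tables.
#'
#' @param slopes slope table from [fit_all_slopes()] or
#'   [read_slope_sheet()] (wide parameter columns are accepted).
#' @param alpha significance level.
#' @return data.frame with one row per parameter: test used, transform,
#'   statistic, dfs, p, and assumption flags; the full `group_test`
#'   objects are attached as attribute `"tests"`.
#' @export
compare_slopes <- function(slopes, alpha = 0.05) {
  stopifnot("condition" %in% names(slopes))
  grp_lab <- if ("zt" %in% names(slopes)) {
    paste(slopes$condition, slopes$zt)
  } else slopes$condition
  long <- "parameter" %in% names(slopes) &&
    ("gated_slope" %in% names(slopes) || "slope" %in% names(slopes))
  params <- if (long) unique(slopes$parameter)
  else intersect(FEATURE_COLS, names(slopes))
  tests <- list()
  rows <- list()
  for (p in params) {
    if (long) {
      sel <- slopes$parameter == p
      vals <- slopes$gated_slope %||% slopes$slope
      vals <- vals[sel]
      gl <- grp_lab[sel]
    } else {
      vals <- slopes[[p]]
      gl <- grp_lab
    }
    ok <- !is.na(vals)
    gt <- run_group_comparison(split(vals[ok], gl[ok]), alpha = alpha)
    tests[[p]] <- gt
    rows[[p]] <- data.frame(
      parameter = p, test = gt$test, transform = gt$transform,
      normality = ifelse(gt$normality_pass, "Pass", "Fail"),
      variance = ifelse(gt$variance_pass, "Pass", "Fail"),
      statistic = gt$statistic, df = gt$df_between,
      df_residual = gt$df_residual, p = gt$p)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "tests") <- tests
  out
}
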
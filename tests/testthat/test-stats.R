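test_that("slope fitting and gating follow the t-test rule", {
  tt <- seq(0, 115, by = 5)
  # constant response: slope 0, gated 0
  r <- fit_parameter_slope(tt, rep(4.2, 24))
  expect_equal(r$slope, 0)
  expect_equal(r$gated_slope, 0)
  # exact line: zero-residual slopes count as significant
  r2 <- fit_parameter_slope(tt, 2 + 0.05 * tt)
  expect_equal(r2$slope, 0.05)
  expect_equal(r2$gated_slope, 0.05)
  expect_equal(r2$intercept, 2)
  # < 3 points: missing slope, gate closed
  r3 <- fit_parameter_slope(c(0, 5), c(1, 2))
  expect_true(is.na(r3$slope))
  expect_equal(r3$gated_slope, 0)
  expect_error(fit_parameter_slope(rep(1, 5), 1:5), "variance")
  # missing values are dropped pairwise
  r4 <- fit_parameter_slope(c(tt, 120), c(2 + 0.05 * tt, NA))
  expect_equal(r4$n_points, 24)
  expect_equal(r4$slope, 0.05)
})

test_that("gating decisions match an independent OLS + t oracle", {
  tt <- seq(0, 115, by = 5)
  for (s in 1:100) {
    set.seed(s)
    y <- 0.05 * tt + rnorm(24, sd = 2)
    r <- fit_parameter_slope(tt, y)
    o <- oracle_slope(tt, y)
    expect_equal(r$slope, o$slope, tolerance = 1e-12)
    expect_equal(r$p_slope, o$p, tolerance = 1e-12)
    expect_identical(r$gated_slope == 0, o$p >= 0.05)
  }
})

test_that("group comparison handles degenerate and textbook cases", {
  # two identical groups
  gt <- run_group_comparison(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p, 1)
  # four small integer groups vs the base-R ANOVA oracle
  groups <- list(a = c(1, 3, 2, 4), b = c(5, 4, 6, 7),
                 c = c(2, 2, 3, 1), d = c(8, 9, 7, 9))
  gt2 <- run_group_comparison(groups)
  o <- oracle_anova_f(groups)
  expect_equal(gt2$statistic, o$f, tolerance = 1e-12)
  expect_equal(gt2$p, o$p, tolerance = 1e-12)
  expect_equal(gt2$df_between, 3)
  expect_equal(gt2$df_residual, 12)
  expect_error(run_group_comparison(list(a = 1:3)), "two groups")
  expect_error(run_group_comparison(list(a = 1:3, b = 2)), "two values")
})

test_that("decision tree branches are exclusive and post hoc matches branch", {
  set.seed(5)
  # normal, equal variance: parametric branch, Tukey
  g_norm <- list(a = rnorm(12), b = rnorm(12, 1), c = rnorm(12, 2))
  r1 <- run_group_comparison(g_norm)
  expect_match(r1$test, "ANOVA$")
  expect_true(all(r1$posthoc$method == "Tukey"))
  # heavy-tailed with non-positive values: rank branch, Dunn
  g_heavy <- list(a = c(-5, rcauchy(14)), b = rcauchy(15, 3),
                  c = c(0, rcauchy(14)))
  r2 <- run_group_comparison(g_heavy)
  expect_match(r2$test, "ranks")
  expect_true(all(r2$posthoc$method == "Dunn"))
  expect_true(is.na(r2$df_residual))
  # log-normal with spread means: log branch repairs normality
  g_ln <- list(a = exp(rnorm(15, 0, 1)), b = exp(rnorm(15, 2, 1)),
               c = exp(rnorm(15, 4, 1)))
  r3 <- run_group_comparison(g_ln)
  if (r3$transform == "log") {
    expect_match(r3$test, "ANOVA$")
    expect_equal(r3$statistic,
                 oracle_anova_f(lapply(g_ln, log))$f, tolerance = 1e-9)
  } else {
    expect_match(r3$test, "ranks")
  }
  # transform_policy = "none" skips the log branch entirely
  r4 <- run_group_comparison(g_ln, transform_policy = "none")
  expect_match(r4$test, "ranks")
})

test_that("F and H statistics match brute-force oracles on random data", {
  set.seed(17)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) {
      round(rnorm(sample(3:8, 1), mean = j), 1) # ties occur
    })
    names(groups) <- paste0("g", seq_len(k))
    o_f <- oracle_anova_f(groups)
    st <- ssrquant:::oneway_anova_stats(groups)
    expect_lt(abs(st$f - o_f$f), 1e-9)
    y <- unlist(groups)
    g <- factor(rep(names(groups), lengths(groups)))
    h_pkg <- unname(stats::kruskal.test(y, g)$statistic)
    expect_lt(abs(h_pkg - oracle_kw_h(groups)), 1e-9)
  }
})

test_that("RM ANOVA equals the sum-of-squares oracle and handles nulls", {
  # all within-animal differences zero
  d0 <- expand.grid(animal = paste0("a", 1:6),
                    condition = c("ctrl", "tox1", "tox2"))
  d0$value <- rep(1:6, 3) # pure animal effect, no condition effect
  r0 <- run_rm_comparison(d0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # random balanced table vs the textbook decomposition
  set.seed(23)
  for (i in 1:20) {
    a <- sample(4:8, 1)
    k <- sample(2:4, 1)
    m <- matrix(rnorm(a * k, mean = rep(seq_len(k), each = a)), a, k)
    d <- data.frame(animal = rep(paste0("a", 1:a), k),
                    condition = rep(paste0("c", 1:k), each = a),
                    value = as.vector(m))
    r <- run_rm_comparison(d, transform_policy = "none")
    o <- oracle_rm_f(m)
    expect_lt(abs(r$statistic - o$f), 1e-9)
    expect_equal(r$df_between, o$df_between)
    expect_equal(r$df_residual, o$df_residual)
    expect_equal(r$p, o$p, tolerance = 1e-9)
  }
  # an animal with a single condition is excluded with a message
  d1 <- rbind(d0, data.frame(animal = "a7", condition = "ctrl", value = 9))
  expect_message(run_rm_comparison(d1), "a7")
})

test_that("paired toxin cohorts: true effects detected, sham effects not", {
  hits_true <- 0
  hits_sham <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    des <- cohort_design(groups = data.frame(condition = c("tox", "sham"),
                                             zt = "ZT1-3",
                                             n_animals = c(6, 6)),
                         paired = TRUE, stimulus_interval = 60,
                         first_stimulus = 1)
    gts <- list(control = ground_truth_params(),
                tox = ground_truth_params(f_phasic = 80), # strong F6AP drop
                sham = ground_truth_params())
    coh <- generate_cohort(des, gts, seed = 3000 + s)
    agg <- stats::aggregate(f6ap_hz ~ animal_id + condition, data = coh$truth,
                            FUN = mean)
    for (cond in c("tox", "sham")) {
      sub <- agg[agg$animal_id %in%
                   agg$animal_id[agg$condition == cond], ]
      sub <- sub[sub$condition %in% c("control", cond), ]
      r <- run_rm_comparison(data.frame(animal = sub$animal_id,
                                        condition = sub$condition,
                                        value = sub$f6ap_hz))
      if (cond == "tox" && r$p < 0.05) hits_true <- hits_true + 1
      if (cond == "sham" && r$p < 0.05) hits_sham <- hits_sham + 1
    }
  }
  expect_gte(hits_true, 0.9 * n_seeds)
  expect_lte(hits_sham, 0.3 * n_seeds)
})

test_that("slope-table group comparison mirrors the published table layout", {
  set.seed(31)
  # synthetic deposited-layout slope sheet: 4 groups x 9 animals
  sl <- expand.grid(experiment_id = paste0("e", 1:9),
                    condition = c("ctrl", "drug"),
                    zt = c("ZT1-3", "ZT9-11"))
  sl$experiment_id <- paste(sl$condition, sl$zt, sl$experiment_id)
  sl$f6ap_hz <- rnorm(36, ifelse(sl$condition == "drug" &
                                   sl$zt == "ZT1-3", -0.8, 0), 0.3)
  sl$latency_ms <- rnorm(36, 0, 0.1)
  tab <- compare_slopes(sl)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$parameter, c("f6ap_hz", "latency_ms"))
  expect_equal(tab$df[1], 3)
  f6 <- tab[tab$parameter == "f6ap_hz", ]
  expect_lt(f6$p, 0.05)
  lat <- tab[tab$parameter == "latency_ms", ]
  expect_gt(lat$p, 0.05)
  tests <- attr(tab, "tests")
  expect_s3_class(tests$f6ap_hz, "group_test")
})
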
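test_that("one-way ANOVA reproduces the hand-derived decomposition", {
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$ss_between, 13.5)
  expect_identical(r$df_between, 1L)
  expect_equal(r$ss_within, 4)
  expect_identical(r$df_within, 4L)
  expect_equal(r$ms_between, 13.5)
  expect_equal(r$ms_within, 1)
  expect_equal(r$f_statistic, 13.5)
  expect_equal(r$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
})

test_that("equal group means give F = 0, p = 1, no rejection", {
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(r$ss_between, 0)
  expect_equal(r$f_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$reject_null)
})

test_that("degenerate and invalid grouped inputs error clearly", {
  expect_error(one_way_anova(list(a = c(5, 5, 5), b = c(5, 5, 5))),
               "zero within-group variance.*a, b")
  expect_error(one_way_anova(list(a = c(1, 2, 3))), "at least 2 groups")
  expect_error(one_way_anova(list(a = 1, b = 2)), "N - k")
})

test_that("F tail probability is a monotone upper tail and matches the t identity", {
  expect_equal(f_tail_probability(0, 3, 10), 1)
  # F(1, d) upper tail at f equals twice the t(d) upper tail at sqrt(f)
  expect_equal(f_tail_probability(4, 1, 10),
               2 * pt(2, 10, lower.tail = FALSE), tolerance = 1e-12)
  f <- c(0, 0.5, 1, 2, 5, 50, 1e4)
  p <- f_tail_probability(f, 3, 17)
  expect_true(all(diff(p) < 0))
  expect_lt(p[length(p)], 1e-10)
  expect_error(f_tail_probability(1, 0, 5), "degrees of freedom")
  expect_error(f_tail_probability(-1, 1, 5), "non-negative")
})

test_that("SS between + SS within equals total SS on randomized inputs", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:12, 1), mean = rnorm(1)))
    names(groups) <- paste0("g", seq_len(k))
    r <- one_way_anova(groups)
    y <- unlist(groups)
    total <- sum((y - mean(y))^2)
    expect_equal(r$ss_between + r$ss_within, total, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA agrees with stats::aov on 100 random datasets", {
  set.seed(22)
  for (i in 1:100) {
    k <- sample(2:11, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(3:15, 1), mean = rnorm(1, sd = 2), sd = runif(1, 0.5, 2)))
    names(groups) <- paste0("g", seq_len(k))
    r <- one_way_anova(groups)
    ref <- reference_one_way(groups)
    expect_equal(r$f_statistic, ref$f, tolerance = 1e-8)
    expect_equal(r$p_value, ref$p, tolerance = 1e-8)
    expect_equal(r$ss_between, ref$ss_between, tolerance = 1e-8)
    expect_equal(r$ss_within, ref$ss_within, tolerance = 1e-8)
  }
})

test_that("the inverted compatibility decision rule flips the standard one", {
  strong <- one_way_anova(list(a = c(1, 2, 3), b = c(14, 15, 16)))
  expect_true(strong$reject_null)
  expect_false(one_way_anova(list(a = c(1, 2, 3), b = c(14, 15, 16)),
                             decision_rule = "inverted")$reject_null)
  weak <- one_way_anova(list(a = c(1, 2, 3), b = c(1.1, 2.1, 3.1)))
  expect_false(weak$reject_null)
  expect_true(one_way_anova(list(a = c(1, 2, 3), b = c(1.1, 2.1, 3.1)),
                            decision_rule = "inverted")$reject_null)
})

test_that("balanced two-way decomposition matches stats::aov with interaction", {
  set.seed(23)
  for (i in 1:20) {
    a_lv <- sample(2:4, 1); b_lv <- sample(2:5, 1); n <- sample(2:4, 1)
    d <- expand.grid(a = paste0("a", seq_len(a_lv)),
                     b = paste0("b", seq_len(b_lv)),
                     rep = seq_len(n))
    d$y <- rnorm(nrow(d), mean = as.integer(d$a) + 2 * (as.integer(d$b) %% 2))
    r <- two_way_anova(d$y, d$a, d$b, factor_names = c("a", "b"))
    ref <- summary(aov(y ~ a * b, data = d))[[1]]
    expect_equal(r$table$ss[1:3], ref[1:3, "Sum Sq"], tolerance = 1e-8)
    expect_equal(r$table$df[1:3], ref[1:3, "Df"])
    expect_equal(r$table$f_statistic[1:3], ref[1:3, "F value"], tolerance = 1e-8)
    expect_equal(r$table$p_value[1:3], ref[1:3, "Pr(>F)"], tolerance = 1e-8)
    expect_equal(r$table$ss[4], ref[4, "Sum Sq"], tolerance = 1e-8)
    # the decomposition is exhaustive
    expect_equal(sum(r$table$ss), r$ss_total, tolerance = 1e-9)
  }
})

test_that("single-replicate two-way fits the additive model", {
  d <- expand.grid(a = paste0("a", 1:3), b = paste0("b", 1:2))
  set.seed(24)
  d$y <- as.integer(d$a) + 10 * as.integer(d$b) + rnorm(nrow(d), sd = 0.1)
  r <- two_way_anova(d$y, d$a, d$b, factor_names = c("a", "b"))
  expect_identical(r$table$effect, c("a", "b", "residual"))
  expect_identical(r$table$df[r$table$effect == "residual"], 2L)  # (3-1)(2-1)
  ref <- summary(aov(y ~ a + b, data = d))[[1]]
  expect_equal(r$table$ss, ref[, "Sum Sq"], tolerance = 1e-8)
})

test_that("two-way rejects unbalanced or degenerate designs", {
  expect_error(two_way_anova(rnorm(5), c("a", "a", "a", "b", "b"),
                             c("x", "y", "x", "x", "y")),
               "unbalanced")
  d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:2)
  expect_error(two_way_anova(rep(1, 8), d$a, d$b), "degenerate|zero residual")
  expect_error(two_way_anova(rnorm(4), rep("a", 4), c("x", "x", "y", "y")),
               "at least 2 levels")
})

test_that("Tukey HSD matches stats::TukeyHSD and its reject rule is CI-based", {
  set.seed(25)
  for (i in 1:30) {
    k <- sample(3:6, 1)
    balanced <- i %% 2 == 0
    sizes <- if (balanced) rep(sample(4:9, 1), k) else sample(4:9, k, replace = TRUE)
    groups <- lapply(seq_len(k), function(j) rnorm(sizes[j], mean = rnorm(1)))
    names(groups) <- paste0("g", seq_len(k))
    tk <- tukey_hsd(groups)
    ref <- reference_tukey(groups)
    key <- paste0(tk$group_b, "-", tk$group_a)
    expect_equal(tk$meandiff, unname(ref[key, "diff"]), tolerance = 1e-8)
    expect_equal(tk$lower, unname(ref[key, "lwr"]), tolerance = 1e-8)
    expect_equal(tk$upper, unname(ref[key, "upr"]), tolerance = 1e-8)
    expect_identical(tk$reject, tk$lower > 0 | tk$upper < 0)
    expect_true(all(tk$lower <= tk$meandiff & tk$meandiff <= tk$upper))
  }
})

test_that("Tukey flags exactly the pairs involving one strongly shifted group", {
  set.seed(26)
  groups <- list(g1 = rnorm(12), g2 = rnorm(12), g3 = rnorm(12) + 50)
  tk <- tukey_hsd(groups)
  involving3 <- tk$group_a == "g3" | tk$group_b == "g3"
  expect_true(all(tk$reject[involving3]))
  expect_false(any(tk$reject[!involving3]))
  # identical groups: interval straddles zero
  tk0 <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(tk0$meandiff, 0)
  expect_true(tk0$lower < 0 && tk0$upper > 0)
  expect_false(tk0$reject)
})

test_that("rejection rate grows with the planted mean shift", {
  set.seed(27)
  rate <- vapply(c(0, 0.7, 1.6), function(shift) {
    rej <- vapply(1:300, function(i) {
      groups <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + shift)
      one_way_anova(groups)$reject_null
    }, logical(1))
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_lt(rate[1], 0.12)
  expect_gt(rate[3], 0.8)
})

test_that("no Tukey rejection usually coincides with a non-significant F", {
  set.seed(28)
  n_sim <- 400
  no_tukey <- 0L; agree <- 0L
  for (i in seq_len(n_sim)) {
    groups <- lapply(1:4, function(j) rnorm(8))
    names(groups) <- paste0("g", 1:4)
    tk <- tukey_hsd(groups)
    if (!any(tk$reject)) {
      no_tukey <- no_tukey + 1L
      if (one_way_anova(groups)$p_value > 0.05) agree <- agree + 1L
    }
  }
  expect_gt(no_tukey, 0L)
  expect_gte(agree / no_tukey, 0.95)
})

test_that("windowed counts partition occurrence starts by half-open windows", {
  set.seed(29)
  bg <- generate_background(10000, seed = 29, forbid = "TAGA")
  planted <- plant_runs(bg, "TAGA",
                        data.frame(start = c(0L, 996L, 1000L, 5000L, 9500L),
                                   copies = 1L))
  g <- genome_sequence("w", planted$sequence)
  wc <- windowed_counts(g, "TAGA", 1000)
  expect_identical(dim(wc), c(1L, 10L))
  # start 996 is in window 1; start 1000 sits exactly on the boundary and
  # belongs to window 2 (half-open convention)
  expect_identical(unname(wc[1, ]), c(2L, 1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L))
  expect_identical(sum(wc), length(planted$truth_starts))
  expect_error(windowed_counts(g, "TAGA", 20000), "exceeds genome length")
  expect_error(windowed_counts(g, "TAGA", 30), "10 times")
})

test_that("occurrences in the dropped trailing partial window are dropped", {
  bg <- generate_background(1050, seed = 30, forbid = "TAGA")
  planted <- plant_runs(bg, "TAGA", data.frame(start = c(100L, 1020L), copies = 1L))
  g <- genome_sequence("w", planted$sequence)
  wc <- windowed_counts(g, "TAGA", 1000)
  expect_identical(dim(wc), c(1L, 1L))
  expect_identical(sum(wc), 1L)
})
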
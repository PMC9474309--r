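# One-way / two-way ANOVA and Tukey HSD built from the sum-of-squares
# decomposition, plus the windowed count matrices that serve as observation
# units when comparing SSR abundance across genomes and motifs.

validate_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least 2 groups of observations are required", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs at least one observation", call. = FALSE)
  if (any(!vapply(groups, function(g) all(is.finite(g)), logical(1))))
    stop("observations must be finite", call. = FALSE)
  groups
}

#' Upper-tail probability of the F distribution
#'
#' `P(F_{df1, df2} >= f)`; monotone non-increasing in `f`, 1 at `f = 0`.
#'
#' @param f Observed F statistic, `f >= 0`.
#' @param df1,df2 Numerator / denominator degrees of freedom, `>= 1`.
#' @return Tail probability in \[0, 1\].
#' @export
f_tail_probability <- function(f, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1", call. = FALSE)
  if (any(f < 0)) stop("F statistic must be non-negative", call. = FALSE)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' One-way analysis of variance from the sum-of-squares decomposition
#'
#' Tests equality of k group means. Between-group variability is
#' `SS_between = sum_i n_i (xbar_i - xbar_G)^2` on `k - 1` degrees of
#' freedom; within-group variability is
#' `SS_within = sum_ij (x_ij - xbar_i)^2` on `N - k`; the statistic is the
#' ratio of the corresponding mean squares,
#' `F = MS_between / MS_within`, referred to the F distribution.
#'
#' Under the standard decision rule the null (all means equal) is rejected
#' when the upper-tail p-value is below `alpha`, i.e. when F exceeds the
#' critical value. The `"inverted"` compatibility rule instead flags
#' rejection when F falls *below* the critical value; it is provided only
#' to mirror reports that used that inverted convention and is never the
#' default.
#'
#' @param groups Named list of numeric observation vectors (k >= 2).
#' @param alpha Significance level in (0, 1).
#' @param decision_rule `"standard"` (reject when p < alpha) or
#'   `"inverted"` (compatibility; reject when F < F critical).
#' @return Object of class `anova_result`: `ss_between`, `df_between`,
#'   `ms_between`, `ss_within`, `df_within`, `ms_within`, `f_statistic`,
#'   `f_critical`, `p_value`, `reject_null`, `alpha`, `decision_rule`,
#'   `group_means`, `grand_mean`, `n`.
#' @examples
#' r <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' r$f_statistic  # 13.5
#' @export
one_way_anova <- function(groups, alpha = 0.05,
                          decision_rule = c("standard", "inverted")) {
  decision_rule <- match.arg(decision_rule)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  groups <- validate_groups(groups)
  k <- length(groups)
  n_i <- lengths(groups)
  N <- sum(n_i)
  if (N - k < 1L) stop("need N - k >= 1 residual degrees of freedom", call. = FALSE)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n_i * means) / N
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - means[i])^2),
                          numeric(1)))
  if (ss_within <= 0) {
    flat <- names(groups)[vapply(groups, function(g) all(g == g[1]), logical(1))]
    stop(sprintf("degenerate input: zero within-group variance (constant groups: %s)",
                 paste(flat, collapse = ", ")), call. = FALSE)
  }
  df_between <- k - 1L
  df_within <- N - k
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  f <- ms_between / ms_within
  p <- f_tail_probability(f, df_between, df_within)
  f_crit <- stats::qf(1 - alpha, df_between, df_within)
  reject <- if (decision_rule == "standard") p < alpha else f < f_crit
  structure(list(ss_between = ss_between, df_between = df_between,
                 ms_between = ms_between, ss_within = ss_within,
                 df_within = df_within, ms_within = ms_within,
                 f_statistic = f, f_critical = f_crit, p_value = p,
                 reject_null = reject, alpha = alpha,
                 decision_rule = decision_rule,
                 group_means = means, grand_mean = grand, n = n_i),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.6g, p = %.4g (%s rule, alpha = %g) -> %s\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value,
              x$decision_rule, x$alpha,
              if (x$reject_null) "reject null" else "retain null"))
  invisible(x)
}

#' Balanced two-way analysis of variance
#'
#' Decomposes variance into two categorical main effects, their interaction
#' (when every cell has at least two replicates) and residual, for a
#' balanced design (equal replicates in every factor-level combination).
#' With a single replicate per cell the additive model is fitted and the
#' interaction term is absorbed into the residual on
#' `(a - 1)(b - 1)` degrees of freedom. Each effect's F statistic is its
#' mean square over the residual mean square, with the same upper-tail
#' p-value as [one_way_anova()].
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factor labels, one per observation; at least 2
#'   levels each.
#' @param alpha Significance level.
#' @param factor_names Labels used in the output rows.
#' @return Object of class `two_way_anova_result` with a `table` data frame
#'   (rows per effect and residual: `effect`, `ss`, `df`, `ms`,
#'   `f_statistic`, `p_value`, `reject_null`) plus `alpha`, `replicates`.
#' @export
two_way_anova <- function(values, factor_a, factor_b, alpha = 0.05,
                          factor_names = c("A", "B")) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b),
            is.numeric(alpha), alpha > 0, alpha < 1)
  values <- as.numeric(values)
  fa <- factor(factor_a); fb <- factor(factor_b)
  a <- nlevels(fa); b <- nlevels(fb)
  if (a < 2L || b < 2L) stop("each factor needs at least 2 levels", call. = FALSE)
  cell_n <- table(fa, fb)
  if (length(unique(as.vector(cell_n))) != 1L || any(cell_n == 0))
    stop("unbalanced design: every factor-level combination needs the same number of replicates",
         call. = FALSE)
  n <- as.integer(cell_n[1, 1])
  grand <- mean(values)
  mean_a <- tapply(values, fa, mean)
  mean_b <- tapply(values, fb, mean)
  cell_means <- tapply(values, list(fa, fb), mean)
  ss_total <- sum((values - grand)^2)
  ss_a <- b * n * sum((mean_a - grand)^2)
  ss_b <- a * n * sum((mean_b - grand)^2)
  ss_cells <- n * sum((cell_means - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  with_interaction <- n >= 2L
  if (with_interaction) {
    ss_resid <- ss_total - ss_cells
    df_resid <- a * b * (n - 1L)
    effects <- data.frame(effect = c(factor_names, paste(factor_names, collapse = ":")),
                          ss = c(ss_a, ss_b, ss_ab),
                          df = c(a - 1L, b - 1L, (a - 1L) * (b - 1L)),
                          stringsAsFactors = FALSE)
  } else {
    ss_resid <- ss_total - ss_a - ss_b   # interaction absorbed into residual
    df_resid <- (a - 1L) * (b - 1L)
    effects <- data.frame(effect = factor_names,
                          ss = c(ss_a, ss_b),
                          df = c(a - 1L, b - 1L),
                          stringsAsFactors = FALSE)
  }
  if (df_resid < 1L) stop("residual degrees of freedom must be >= 1", call. = FALSE)
  ms_resid <- ss_resid / df_resid
  if (ms_resid <= 0)
    stop("degenerate input: zero residual variance in two-way design", call. = FALSE)
  effects$ms <- effects$ss / effects$df
  effects$f_statistic <- effects$ms / ms_resid
  effects$p_value <- f_tail_probability(effects$f_statistic, effects$df, df_resid)
  effects$reject_null <- effects$p_value < alpha
  tab <- rbind(effects,
               data.frame(effect = "residual", ss = ss_resid, df = df_resid,
                          ms = ms_resid, f_statistic = NA_real_,
                          p_value = NA_real_, reject_null = NA,
                          stringsAsFactors = FALSE))
  structure(list(table = tab, alpha = alpha, replicates = n,
                 ss_total = ss_total), class = "two_way_anova_result")
}

#' @export
print.two_way_anova_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (balanced, %d replicate(s)/cell, alpha = %g)\n",
              x$replicates, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD all-pairs comparisons
#'
#' For every unordered pair of groups, the mean difference
#' `xbar_b - xbar_a` with a simultaneous confidence interval of half-width
#' `q(1 - alpha, k, df_within) / sqrt(2) * sqrt(MS_within (1/n_a + 1/n_b))`
#' where q is the studentized range quantile (the Tukey-Kramer form, exact
#' for equal group sizes). A pair is rejected exactly when its interval
#' excludes zero, which controls the family-wise error rate at
#' `family_alpha`.
#'
#' @param groups Named list of numeric observation vectors (k >= 2).
#' @param family_alpha Family-wise significance level.
#' @return Data frame of class `tukey_comparisons`: `group_a`, `group_b`,
#'   `meandiff`, `lower`, `upper`, `reject`; attribute `family_alpha`.
#' @export
tukey_hsd <- function(groups, family_alpha = 0.05) {
  aov1 <- one_way_anova(groups, alpha = family_alpha)
  groups <- validate_groups(groups)
  k <- length(groups)
  labs <- names(groups)
  n_i <- aov1$n
  means <- aov1$group_means
  qcrit <- stats::qtukey(1 - family_alpha, nmeans = k, df = aov1$df_within)
  pairs <- utils::combn(k, 2)
  res <- data.frame(
    group_a = labs[pairs[1, ]],
    group_b = labs[pairs[2, ]],
    meandiff = unname(means[pairs[2, ]] - means[pairs[1, ]]),
    stringsAsFactors = FALSE
  )
  half <- qcrit / sqrt(2) *
    sqrt(aov1$ms_within * (1 / n_i[pairs[1, ]] + 1 / n_i[pairs[2, ]]))
  res$lower <- res$meandiff - half
  res$upper <- res$meandiff + half
  res$reject <- res$lower > 0 | res$upper < 0
  rownames(res) <- NULL
  structure(res, family_alpha = family_alpha,
            class = c("tukey_comparisons", "data.frame"))
}

#' Per-window motif counts for one genome
#'
#' Partitions the genome into non-overlapping windows `[i*w, (i+1)*w)`
#' (0-based, half-open; the trailing partial window is dropped) and counts
#' occurrences of each motif by the window containing their start. The
#' windows are the replicate observation units fed to the ANOVA layer.
#'
#' @param genome A `genome_sequence`.
#' @param motifs Character vector of motifs or list of `motif_pattern`s.
#' @param window_size Window width in bases; at least 10 times the longest
#'   motif and at most the genome length.
#' @return Integer matrix, motifs x windows (columns `w1`, `w2`, ...).
#' @export
windowed_counts <- function(genome, motifs, window_size) {
  stopifnot(inherits(genome, "genome_sequence"),
            is.numeric(window_size), length(window_size) == 1L)
  pats <- lapply(motifs, as_motif_pattern)
  max_m <- max(vapply(pats, `[[`, integer(1), "m"))
  if (window_size < 10 * max_m)
    stop("window_size must be at least 10 times the motif length", call. = FALSE)
  if (window_size > genome$length)
    stop(sprintf("window_size (%d) exceeds genome length (%d)",
                 as.integer(window_size), genome$length), call. = FALSE)
  w <- as.integer(window_size)
  n_win <- genome$length %/% w
  out <- matrix(0L, nrow = length(pats), ncol = n_win,
                dimnames = list(vapply(pats, `[[`, "", "motif"),
                                paste0("w", seq_len(n_win))))
  for (i in seq_along(pats)) {
    st <- find_occurrences(genome, pats[[i]])
    if (length(st)) {
      win <- st %/% w + 1L
      win <- win[win <= n_win]          # starts in the dropped tail are dropped
      tab <- tabulate(win, nbins = n_win)
      out[i, ] <- tab
    }
  }
  out
}
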
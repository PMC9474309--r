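# Independent oracles used across the suite. Deliberately simple and
# package-independent: base-R substring scans and stats::aov / TukeyHSD.

# all 0-based occurrence starts by comparing every alignment's substring
oracle_scan <- function(text, motif) {
  n <- nchar(text); m <- nchar(motif)
  if (m == 0L || m > n) return(integer(0))
  i <- seq_len(n - m + 1L)
  i[substring(text, i, i + m - 1L) == motif] - 1L
}

# smallest 0-based offset whose final character aligns with motif's last
oracle_first_align <- function(text, motif) {
  n <- nchar(text); m <- nchar(motif)
  if (m > n) return(NA_integer_)
  last <- substr(motif, m, m)
  i <- seq.int(m, n)
  hit <- i[substring(text, i, i) == last]
  if (!length(hit)) NA_integer_ else hit[1] - m
}

# motif period: smallest shift under which the motif self-overlaps
oracle_period <- function(motif) {
  m <- nchar(motif)
  p <- strsplit(motif, "", fixed = TRUE)[[1]]
  for (s in seq_len(m)) {
    i <- seq_len(m - s)
    if (s == m || all(p[i] == p[i + s])) return(s)
  }
  m
}

# brute-force border array: longest proper prefix that is also a suffix
oracle_prefix_function <- function(motif) {
  m <- nchar(motif)
  vapply(seq_len(m), function(i) {
    pre <- substr(motif, 1L, i)
    for (l in rev(seq_len(i - 1L))) {
      if (substr(pre, 1L, l) == substr(pre, i - l + 1L, i)) return(l)
    }
    0L
  }, integer(1))
}

random_dna <- function(n, with_n = FALSE) {
  ab <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  pr <- if (with_n) c(.24, .24, .24, .24, .04) else rep(.25, 4)
  paste(sample(ab, n, replace = TRUE, prob = pr), collapse = "")
}

# reference one-way ANOVA via stats::aov
reference_one_way <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  tab <- summary(stats::aov(y ~ g))[[1]]
  list(f = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       ss_between = tab[1, "Sum Sq"], ss_within = tab[2, "Sum Sq"])
}

reference_tukey <- function(groups, alpha = 0.05) {
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  stats::TukeyHSD(stats::aov(y ~ g), conf.level = 1 - alpha)$g
}
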
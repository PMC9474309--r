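# Synthetic genomes with planted SSR runs and exact truth tables.
#
# Backgrounds are i.i.d. nucleotides with a target GC fraction from which
# every panel motif has been scrubbed (local re-roll), so the only motif
# occurrences in a generated genome are the ones implied by the planted
# tandem runs: the runs themselves, the overlaps implied by motif
# periodicity, and occurrences of one motif inside a run of a rotated
# motif (a TAGA tract contains GATA and AGAT). Tract/background junctions
# are re-rolled too, which turns integration tests into exact equality
# assertions against the truth table.

rebuild_string <- function(chars) paste(chars, collapse = "")

scrub_motifs <- function(chars, forbid, protect = integer(0), probs,
                         max_passes = 100L) {
  # re-roll any position of a forbidden-motif occurrence that is not
  # protected (protected = inside a planted interval); 1-based indices
  alphabet <- c("A", "C", "G", "T")
  protect_mask <- logical(length(chars))
  protect_mask[protect] <- TRUE
  for (pass in seq_len(max_passes)) {
    bad <- integer(0)
    text <- rebuild_string(chars)
    for (f in forbid) {
      hits <- .naive_scan_cpp(text, f)          # 0-based
      if (length(hits)) {
        m <- nchar(f)
        fixable <- vapply(hits, function(s) !all(protect_mask[(s + 1L):(s + m)]),
                          logical(1))
        bad <- c(bad, unlist(lapply(hits[fixable],
                                    function(s) (s + 1L):(s + m))))
      }
    }
    bad <- setdiff(unique(bad), which(protect_mask))
    if (!length(bad)) return(chars)
    chars[bad] <- sample(alphabet, length(bad), replace = TRUE, prob = probs)
  }
  stop(sprintf("could not scrub forbidden motifs after %d passes", max_passes),
       call. = FALSE)
}

#' Generate an i.i.d. background sequence free of forbidden motifs
#'
#' Draws residues independently with `P(G) + P(C) = gc_fraction` (split
#' evenly within GC and within AT) and locally re-rolls any accidental
#' occurrence of a forbidden motif until the background contains none, so
#' truth tables built on top of it are exact. Fully determined by `seed`.
#'
#' @param length Sequence length (>= 0).
#' @param gc_fraction GC proportion in \[0, 1\].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param forbid Character vector of motifs that must not occur.
#' @param max_passes Re-roll passes before giving up (near-impossible
#'   forbid sets, e.g. all four homopolymers on a long sequence, can fail).
#' @return Residue text of the requested length.
#' @export
generate_background <- function(length, gc_fraction = 0.4, seed = NULL,
                                forbid = character(0), max_passes = 100L) {
  stopifnot(length >= 0, gc_fraction >= 0, gc_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (length == 0) return("")
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = probs)
  if (length(forbid))
    chars <- scrub_motifs(chars, toupper(forbid), probs = probs,
                          max_passes = max_passes)
  rebuild_string(chars)
}

#' Plant tandem motif runs into a background sequence
#'
#' Writes `copies` tandem copies of `motif` at each requested 0-based
#' `start` and returns the resulting sequence together with the exact
#' truth table of occurrence starts: a naive scan of the final sequence
#' restricted to the planted intervals, so overlapping occurrences implied
#' by motif periodicity (e.g. ATAT x2 -> starts 0, 2, 4) are included.
#' Runs must not overlap and must fit inside the background. Note that an
#' arbitrary background can still yield accidental occurrences spanning a
#' tract/background junction; those are outside the planted intervals and
#' hence not part of the truth table. [generate_panel()] additionally
#' re-rolls junction bases so that no such accidental occurrence survives.
#'
#' @param background Residue text (typically from [generate_background()]
#'   with this motif forbidden).
#' @param motif Motif text.
#' @param runs Data frame with columns `start` (0-based) and `copies`
#'   (>= 1).
#' @return List with `sequence`, `truth_starts` (0-based, ascending) and
#'   `intervals` (data frame `start`, `end`, 0-based half-open).
#' @export
plant_runs <- function(background, motif, runs) {
  stopifnot(is.character(background), length(background) == 1L,
            is.data.frame(runs), all(c("start", "copies") %in% names(runs)))
  motif <- toupper(motif)
  m <- nchar(motif)
  if (nrow(runs) == 0L)
    return(list(sequence = background, truth_starts = integer(0),
                intervals = data.frame(start = integer(), end = integer())))
  if (any(runs$copies < 1L)) stop("copies must be >= 1", call. = FALSE)
  runs <- runs[order(runs$start), , drop = FALSE]
  spans <- runs$copies * m
  ends <- runs$start + spans
  if (any(runs$start < 0L) || any(ends > nchar(background)))
    stop("planted runs must fit inside the background", call. = FALSE)
  if (nrow(runs) > 1L && any(runs$start[-1] < ends[-length(ends)]))
    stop("planted runs overlap", call. = FALSE)
  chars <- strsplit(background, "", fixed = TRUE)[[1]]
  mot_chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  for (r in seq_len(nrow(runs)))
    chars[(runs$start[r] + 1L):ends[r]] <-
      rep(mot_chars, times = runs$copies[r])
  sequence <- rebuild_string(chars)
  truth <- truth_scan(sequence, motif,
                      data.frame(start = runs$start, end = ends))
  list(sequence = sequence, truth_starts = truth,
       intervals = data.frame(start = runs$start, end = ends))
}

truth_scan <- function(sequence, motif, intervals) {
  # naive occurrences of motif lying entirely inside the union of planted
  # intervals (mask semantics: adjacent tracts merge)
  m <- nchar(motif)
  hits <- .naive_scan_cpp(sequence, motif)
  if (!length(hits) || !nrow(intervals)) return(integer(0))
  mask <- logical(nchar(sequence))
  for (r in seq_len(nrow(intervals)))
    mask[(intervals$start[r] + 1L):intervals$end[r]] <- TRUE
  inside <- vapply(hits, function(s) all(mask[(s + 1L):(s + m)]), logical(1))
  hits[inside]
}

#' Generate a panel of synthetic genomes with controlled SSR densities
#'
#' Emulates a multi-genome SSR study: each genome is an i.i.d. background
#' scrubbed of all panel motifs, into which tandem runs of every motif are
#' planted at Poisson-distributed counts with mean
#' `multiplier[genome, motif] * base_rate_per_mb * genome_length / 1e6`,
#' at uniform non-overlapping positions, with geometrically distributed
#' copy numbers (mean `copies_mean`). Tract/background junctions are
#' re-rolled so that the truth table — a naive scan restricted to planted
#' intervals, which includes periodic overlaps and rotated-motif hits
#' inside foreign tracts — is exactly the set of occurrences present.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param motifs Motif panel (default the ten 4-bp SSRs).
#' @param multipliers Per-genome density multipliers: numeric vector of
#'   length `n_genomes`, or a `n_genomes x length(motifs)` matrix for
#'   per-motif control. All values >= 0.
#' @param genome_length Length of every genome in bases.
#' @param base_rate_per_mb Expected planted runs per motif per megabase at
#'   multiplier 1.
#' @param copies_mean Mean tandem copies per planted run (>= 1);
#'   `copies = 1 + rgeom` with matching mean, capped at 30.
#' @param gc_fraction Background GC proportion.
#' @param seed Integer seed; fully determines the panel.
#' @param dir If non-NULL, write `genome<i>.fa` FASTA files and
#'   `truth.tsv` (columns genome_id, motif, start) into this directory.
#' @return List with `genomes` (list of `genome_sequence`), `truth` (data
#'   frame `genome_id`, `motif`, `start`), `truth_counts` (genome x motif
#'   integer matrix), and `files` (paths, when `dir` is given).
#' @export
generate_panel <- function(n_genomes, motifs = DEFAULT_MOTIFS,
                           multipliers = rep(1, n_genomes),
                           genome_length = 4e5, base_rate_per_mb = 25,
                           copies_mean = 2.5, gc_fraction = 0.4,
                           seed = NULL, dir = NULL) {
  stopifnot(n_genomes >= 1, genome_length >= 1000, base_rate_per_mb >= 0,
            copies_mean >= 1)
  motifs <- toupper(motifs)
  if (anyDuplicated(motifs)) stop("motifs must be unique", call. = FALSE)
  if (is.matrix(multipliers)) {
    stopifnot(nrow(multipliers) == n_genomes, ncol(multipliers) == length(motifs))
  } else {
    stopifnot(length(multipliers) == n_genomes)
    multipliers <- matrix(multipliers, nrow = n_genomes, ncol = length(motifs))
  }
  if (any(multipliers < 0)) stop("density multipliers must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  genomes <- vector("list", n_genomes)
  truth_rows <- list()
  truth_counts <- matrix(0L, n_genomes, length(motifs),
                         dimnames = list(paste0("genome", seq_len(n_genomes)),
                                         motifs))
  geom_p <- 1 / copies_mean            # mean of 1 + rgeom(p) is 1/p
  for (g in seq_len(n_genomes)) {
    bg <- generate_background(genome_length, gc_fraction = gc_fraction,
                              forbid = motifs)
    chars <- strsplit(bg, "", fixed = TRUE)[[1]]
    occupied <- logical(genome_length)
    intervals <- list()
    for (p in seq_along(motifs)) {
      m <- nchar(motifs[p])
      mot_chars <- strsplit(motifs[p], "", fixed = TRUE)[[1]]
      n_runs <- stats::rpois(1, multipliers[g, p] * base_rate_per_mb *
                               genome_length / 1e6)
      placed <- 0L
      tries <- 0L
      while (placed < n_runs) {
        if (tries > 200L * n_runs + 1000L)
          stop("could not place planted runs without overlap (density too high)",
               call. = FALSE)
        tries <- tries + 1L
        copies <- min(1L + stats::rgeom(1, geom_p), 30L)
        span <- copies * m
        if (span > genome_length) next
        start <- sample.int(genome_length - span + 1L, 1L) - 1L  # 0-based
        span_idx <- (start + 1L):(start + span)
        if (any(occupied[span_idx])) next
        occupied[span_idx] <- TRUE
        chars[span_idx] <- rep(mot_chars, times = copies)
        intervals[[length(intervals) + 1L]] <-
          data.frame(start = start, end = start + span)
        placed <- placed + 1L
      }
    }
    ivals <- if (length(intervals)) do.call(rbind, intervals)
             else data.frame(start = integer(), end = integer())
    chars <- scrub_motifs(chars, motifs, protect = which(occupied),
                          probs = probs)
    sequence <- rebuild_string(chars)
    gid <- paste0("genome", g)
    genomes[[g]] <- genome_sequence(gid, sequence)
    for (p in seq_along(motifs)) {
      tstarts <- truth_scan(sequence, motifs[p], ivals)
      truth_counts[g, p] <- length(tstarts)
      if (length(tstarts))
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(genome_id = gid, motif = motifs[p], start = tstarts,
                     stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
           else data.frame(genome_id = character(), motif = character(),
                           start = integer())
  rownames(truth) <- NULL
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- character(n_genomes)
    for (g in seq_len(n_genomes)) {
      fa[g] <- file.path(dir, sprintf("genome%d.fa", g))
      writeLines(c(paste0(">", genomes[[g]]$id, " synthetic"),
                   gsub("(.{70})", "\\1\n", genomes[[g]]$residues, perl = TRUE)),
                 fa[g])
    }
    tf <- file.path(dir, "truth.tsv")
    utils::write.table(truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list(fasta = fa, truth = tf)
  }
  list(genomes = genomes, truth = truth, truth_counts = truth_counts,
       files = files)
}
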
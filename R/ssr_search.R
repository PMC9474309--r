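# Boyer-Moore exact-match engine for SSR motifs: shift-table preprocessing
# (bad character, good suffix via border arrays), first-occurrence
# short-circuit, occurrence enumeration, counting and tandem-run merging.
#
# Conventions: 0-based occurrence starts; the good-suffix table has m + 1
# entries where entry 0 is the shift after a full match (the motif period)
# and entry j the shift after a mismatch at 1-based motif position j.

#' Bad-character shift table
#'
#' For each alphabet character `a`, the largest 0-based index `i` with
#' `motif[i] == a`, or -1 when `a` does not occur in the motif. On a
#' mismatch against text character `c` at 0-based motif index `j`, the
#' bad-character shift is `j - beta[c]`. Text characters outside the
#' alphabet (notably `N`) behave as -1 and can never match.
#'
#' @param motif Non-empty motif over \{A,C,G,T\}.
#' @param alphabet Character vector of alphabet symbols.
#' @return Named integer vector over `alphabet`.
#' @examples
#' bad_character_table("TAGA")  # A=3, C=-1, G=2, T=0
#' @export
bad_character_table <- function(motif, alphabet = c("A", "C", "G", "T")) {
  stopifnot(is.character(motif), length(motif) == 1L, nchar(motif) >= 1L)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  beta <- vapply(alphabet, function(a) {
    hit <- which(chars == a)
    if (length(hit)) max(hit) - 1L else -1L
  }, integer(1))
  beta
}

#' Border array (prefix function)
#'
#' `tau[i]` is the length of the longest proper prefix of `motif[1..i]`
#' that is also a suffix of it (the classic KMP failure function), with
#' `tau[1] = 0`.
#'
#' @param motif Non-empty motif text.
#' @return Integer vector of length `nchar(motif)`.
#' @examples
#' prefix_function("ATAT")  # 0 0 1 2
#' @export
prefix_function <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L, nchar(motif) >= 1L)
  p <- strsplit(motif, "", fixed = TRUE)[[1]]
  m <- length(p)
  tau <- integer(m)
  k <- 0L
  for (i in seq_len(m)[-1]) {
    while (k > 0L && p[k + 1L] != p[i]) k <- tau[k]
    if (p[k + 1L] == p[i]) k <- k + 1L
    tau[i] <- k
  }
  tau
}

#' Strong good-suffix shift table
#'
#' Returns the length-(m+1) shift table gamma. Conceptually indexed 0..m:
#' gamma\[0\] is the shift after a full match and equals the motif period
#' `m - tau[m]` (so overlapping occurrences of periodic motifs are never
#' skipped), and gamma\[j\] the shift after a mismatch at 1-based motif
#' position j. Built from the border array of the motif and of its
#' reversal; every shift lies in \[1, m\].
#'
#' @param motif Non-empty motif over \{A,C,G,T\}.
#' @return Integer vector of length `nchar(motif) + 1`; element 1 is
#'   gamma\[0\].
#' @examples
#' good_suffix_table("ATAT")[1]  # 2: period of ATAT
#' @export
good_suffix_table <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L, nchar(motif) >= 1L)
  m <- nchar(motif)
  tau <- prefix_function(motif)
  tau_rev <- prefix_function(paste(rev(strsplit(motif, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  gamma <- rep.int(m - tau[m], m + 1L)  # index j stored at gamma[j + 1]
  for (l in seq_len(m)) {
    j <- m - tau_rev[l]
    shift <- l - tau_rev[l]
    if (gamma[j + 1L] > shift) gamma[j + 1L] <- shift
  }
  gamma
}

#' Prepare a motif for Boyer-Moore scanning
#'
#' Validates the motif (non-empty, \{A,C,G,T\} only — `N` is not allowed in
#' motifs) and precomputes the bad-character table, the good-suffix table
#' and the border arrays of the motif and its reversal.
#'
#' @param motif Motif text; lowercase accepted.
#' @return Object of class `motif_pattern` with fields `motif`, `m`,
#'   `bad_char`, `good_suffix`, `prefix_fn`, `prefix_fn_rev`.
#' @export
motif_pattern <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L)
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif))
    stop(sprintf("motif '%s' must be non-empty over {A,C,G,T}", motif), call. = FALSE)
  structure(list(
    motif = motif,
    m = nchar(motif),
    bad_char = bad_character_table(motif),
    good_suffix = good_suffix_table(motif),
    prefix_fn = prefix_function(motif),
    prefix_fn_rev = prefix_function(paste(rev(strsplit(motif, "", fixed = TRUE)[[1]]),
                                          collapse = ""))
  ), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (m = %d, period = %d)\n",
              x$motif, x$m, x$good_suffix[1]))
  invisible(x)
}

as_motif_pattern <- function(motif) {
  if (inherits(motif, "motif_pattern")) motif else motif_pattern(motif)
}

as_residue_text <- function(text) {
  if (inherits(text, "genome_sequence")) text$residues else {
    stopifnot(is.character(text), length(text) == 1L)
    text
  }
}

#' First alignment offset where the motif's final character matches
#'
#' Scans the text left to right for the first position at which the motif's
#' rightmost character aligns with an equal text character, i.e. the
#' smallest offset `i` (0-based) with `text[i + m - 1] == motif[m - 1]`.
#' If the final character never occurs at an align-able position the motif
#' cannot occur at all and `NA` ("absent") is returned, which
#' short-circuits [find_occurrences()] to an empty result. A text shorter
#' than the motif also yields `NA`.
#'
#' @param text Residue text or `genome_sequence`.
#' @param motif Motif text or `motif_pattern`.
#' @return 0-based integer offset, or `NA_integer_` when absent.
#' @examples
#' first_occurrence_position("CCCCTAGA", "TAGA")  # 2: text[5] == 'A'
#' @export
first_occurrence_position <- function(text, motif) {
  text <- as_residue_text(text)
  pat <- as_motif_pattern(motif)
  n <- nchar(text); m <- pat$m
  if (m > n) return(NA_integer_)
  last <- substr(pat$motif, m, m)
  k <- regexpr(last, substr(text, m, n), fixed = TRUE)
  if (k == -1L) NA_integer_ else as.integer(k) - 1L
}

#' Find all occurrences of a motif (Boyer-Moore)
#'
#' Enumerates every 0-based offset at which the motif occurs exactly in the
#' text, including overlapping occurrences (the full-match shift equals the
#' motif period). Scanning starts at [first_occurrence_position()] and, on a
#' mismatch at motif position `j`, advances by the maximum of the
#' good-suffix and bad-character shifts; every advance is at least 1.
#' Positions containing `N` never match.
#'
#' @param text Residue text or `genome_sequence`.
#' @param motif Motif text or `motif_pattern`.
#' @return Strictly increasing integer vector of 0-based starts (possibly
#'   empty).
#' @examples
#' find_occurrences("ATATA", "ATA")  # 0 2
#' @export
find_occurrences <- function(text, motif) {
  text <- as_residue_text(text)
  pat <- as_motif_pattern(motif)
  alpha <- first_occurrence_position(text, pat)
  if (is.na(alpha)) return(integer(0))
  .bm_scan_cpp(text, pat$motif, unname(pat$bad_char[c("A", "C", "G", "T")]),
               pat$good_suffix, alpha)
}

#' Naive all-alignments scanner (reference semantics)
#'
#' Checks every alignment of the motif against the text character by
#' character (vectorized candidate filtering). Defines the reference
#' semantics for [find_occurrences()] and is used as its oracle in the test
#' suite.
#'
#' @inheritParams find_occurrences
#' @return Integer vector of 0-based starts, ascending.
#' @export
naive_find_occurrences <- function(text, motif) {
  text <- as_residue_text(text)
  motif <- if (inherits(motif, "motif_pattern")) motif$motif else toupper(motif)
  n <- nchar(text); m <- nchar(motif)
  if (m == 0L || m > n) return(integer(0))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  pat <- strsplit(motif, "", fixed = TRUE)[[1]]
  cand <- seq_len(n - m + 1L)
  for (j in seq_len(m)) {
    cand <- cand[chars[cand + j - 1L] == pat[j]]
    if (!length(cand)) break
  }
  cand - 1L
}

#' Genome-by-motif occurrence count matrix
#'
#' Cell (g, p) is the number of (possibly overlapping) occurrences of motif
#' p in genome g, per [find_occurrences()].
#'
#' @param genomes List of `genome_sequence` objects (or named character
#'   vector of residue texts).
#' @param motifs Character vector of motifs, or list of `motif_pattern`s.
#' @return Integer matrix, rownames genome ids, colnames motifs.
#' @export
count_occurrences <- function(genomes, motifs) {
  if (is.character(genomes)) {
    ids <- if (!is.null(names(genomes))) names(genomes) else paste0("genome", seq_along(genomes))
    genomes <- Map(genome_sequence, ids, genomes)
  }
  if (length(motifs) == 0L) stop("at least one motif is required", call. = FALSE)
  pats <- lapply(motifs, as_motif_pattern)
  counts <- vapply(pats, function(p)
    vapply(genomes, function(g) length(find_occurrences(g, p)), integer(1)),
    integer(length(genomes)))
  counts <- matrix(counts, nrow = length(genomes),
                   dimnames = list(vapply(genomes, `[[`, "", "id"),
                                   vapply(pats, `[[`, "", "motif")))
  counts
}

#' Merge occurrences into tandem runs
#'
#' Maximal chains of occurrences whose consecutive starts differ by exactly
#' the motif length m are merged into runs; a run of `copies` occurrences
#' spans `copies * m` bases (the tract length). Occurrences closer than m
#' (periodic overlaps) or farther apart break the chain.
#'
#' @param starts Ascending integer vector of 0-based occurrence starts.
#' @param m Motif length (bases).
#' @return List with `runs` (data frame `start`, `copies`, `span`) and
#'   `max_run_span` (0 when there is no occurrence).
#' @examples
#' tandem_runs(c(0L, 4L, 8L), 4L)$max_run_span  # 12
#' @export
tandem_runs <- function(starts, m) {
  stopifnot(is.numeric(starts), m >= 1L)
  starts <- as.integer(starts)
  if (is.unsorted(starts, strictly = TRUE) && length(starts) > 1L)
    stop("starts must be strictly increasing", call. = FALSE)
  if (!length(starts))
    return(list(runs = data.frame(start = integer(), copies = integer(),
                                  span = integer()),
                max_run_span = 0L))
  run_id <- cumsum(c(1L, as.integer(diff(starts) != m)))
  first <- starts[!duplicated(run_id)]
  copies <- tabulate(run_id)
  runs <- data.frame(start = first, copies = copies,
                     span = copies * as.integer(m))
  list(runs = runs, max_run_span = max(runs$span))
}

#' Scan one genome for a set of motifs
#'
#' Runs [find_occurrences()] for every motif, attaches tandem-run
#' membership, and produces both the per-occurrence table and the
#' per-motif summary used by the report writers.
#'
#' @param genome A `genome_sequence`.
#' @param motifs Character vector of motifs or list of `motif_pattern`s.
#' @return List with `occurrences` (data frame `sequence_id`, `start`,
#'   `motif`, `run_copies`) and `summary` (data frame `genome_id`, `motif`,
#'   `occurrence_count`, `run_count`, `max_run_span`).
#' @export
scan_genome <- function(genome, motifs) {
  stopifnot(inherits(genome, "genome_sequence"))
  pats <- lapply(motifs, as_motif_pattern)
  occ_list <- vector("list", length(pats))
  summ <- vector("list", length(pats))
  for (i in seq_along(pats)) {
    p <- pats[[i]]
    st <- find_occurrences(genome, p)
    tr <- tandem_runs(st, p$m)
    copies <- integer(length(st))
    if (length(st)) {
      run_id <- cumsum(c(1L, as.integer(diff(st) != p$m)))
      copies <- tr$runs$copies[run_id]
    }
    occ_list[[i]] <- data.frame(sequence_id = rep(genome$id, length(st)),
                                start = st, motif = rep(p$motif, length(st)),
                                run_copies = copies, stringsAsFactors = FALSE)
    summ[[i]] <- data.frame(genome_id = genome$id, motif = p$motif,
                            occurrence_count = length(st),
                            run_count = nrow(tr$runs),
                            max_run_span = tr$max_run_span,
                            stringsAsFactors = FALSE)
  }
  list(occurrences = do.call(rbind, occ_list),
       summary = do.call(rbind, summ))
}
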
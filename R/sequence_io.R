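# FASTA input and BED/TSV result writers.
#
# Coordinates are 0-based half-open internally and in BED output; the
# human-readable summary TSV additionally carries 1-based starts.

#' Normalize raw sequence text to the \{A,C,G,T,N\} alphabet
#'
#' Removes all whitespace (spaces, tabs, line breaks, carriage returns),
#' upper-cases `a/c/g/t/n`, maps `U`/`u` to `T` (RNA input), and keeps `N`
#' (assembly gaps; `N` never matches any motif character during search).
#' Any other character is an error.
#'
#' @param raw Character scalar of raw sequence text.
#' @param what Label used in error messages (e.g. the FASTA record id).
#' @return Validated residue text over \{A,C,G,T,N\}.
#' @examples
#' normalize_sequence("ta ga\n")  # "TAGA"
#' @export
normalize_sequence <- function(raw, what = "sequence") {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- gsub("[ \t\r\n\v\f]", "", raw)
  s <- chartr("acgtnu", "ACGTNT", s)
  s <- chartr("U", "T", s)
  bad <- regexpr("[^ACGTN]", s)
  if (bad != -1L) {
    stop(sprintf("invalid character '%s' at position %d in %s (after whitespace removal); allowed: A,C,G,T,N",
                 substr(s, bad, bad), as.integer(bad), what), call. = FALSE)
  }
  s
}

#' Read genome sequences from a FASTA file
#'
#' Parses a (possibly multi-record, line-wrapped) FASTA file and returns one
#' validated `genome_sequence` per record, in file order. The record id is
#' the first whitespace-delimited token of the header; the rest is kept as
#' the description. Residues are normalized via [normalize_sequence()], so
#' soft-masked (lowercase) bases are searched and `U` is accepted as `T`.
#' Blank lines between records and CRLF line endings are tolerated.
#'
#' @param path Path to a FASTA file (gzip-compressed accepted).
#' @return List of `genome_sequence` objects (fields `id`, `description`,
#'   `residues`, `length`), in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "TAGA", "TAGA"), fa)
#' gs <- read_fasta(fa)
#' gs[[1]]$length  # 8
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- headers[[i]]
    id <- sub("\\s.*$", "", header)
    if (!nzchar(id)) stop(sprintf("record %d of %s has an empty id", i, path), call. = FALSE)
    desc <- sub("^\\S+\\s*", "", header)
    raw <- as.character(set[[i]])
    if (!nzchar(gsub("[ \t\r\n]", "", raw)))
      stop(sprintf("record '%s' in %s has no residues", id, path), call. = FALSE)
    res <- normalize_sequence(raw, what = sprintf("record '%s'", id))
    out[[i]] <- genome_sequence(id, res, description = desc)
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Construct a validated genome sequence
#'
#' @param id Record identifier (non-empty).
#' @param residues Residue text; normalized via [normalize_sequence()].
#' @param description Optional free-text description.
#' @return Object of class `genome_sequence`.
#' @export
genome_sequence <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  res <- normalize_sequence(residues, what = sprintf("record '%s'", id))
  structure(list(id = id, description = description,
                 residues = res, length = nchar(res)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s  (%s bp)%s\n", x$id,
              format(x$length, big.mark = ","),
              if (nzchar(x$description)) paste0("  ", x$description) else ""))
  invisible(x)
}

#' Write motif occurrences as BED6
#'
#' One line per occurrence: sequence id, 0-based start, half-open end
#' (start + motif length), motif as the name field, the number of tandem
#' copies in the run the occurrence belongs to as the score field (a
#' documented reuse of BED score), and '+' strand (scanning is
#' forward-strand only). Lines are sorted by (sequence id, start). An empty
#' occurrence table yields an empty, header-free file.
#'
#' @param occurrences Data frame with columns `sequence_id`, `start`
#'   (0-based), `motif`, and optionally `run_copies` (defaults to '.').
#' @param path Output path.
#' @return Invisibly, the number of lines written.
#' @export
write_occurrences_bed <- function(occurrences, path) {
  stopifnot(is.data.frame(occurrences))
  needed <- c("sequence_id", "start", "motif")
  if (!all(needed %in% names(occurrences)))
    stop("occurrences must have columns sequence_id, start, motif", call. = FALSE)
  occ <- occurrences
  if (nrow(occ) > 0L) {
    m <- nchar(occ$motif)
    if (any(occ$start < 0L)) stop("negative occurrence start", call. = FALSE)
    score <- if ("run_copies" %in% names(occ)) occ$run_copies else rep(".", nrow(occ))
    bed <- data.frame(chrom = occ$sequence_id, start = occ$start,
                      end = occ$start + m, name = occ$motif,
                      score = score, strand = "+", stringsAsFactors = FALSE)
    bed <- bed[order(bed$chrom, bed$start, bed$name), , drop = FALSE]
  } else {
    bed <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = character(), strand = character())
  }
  utils::write.table(bed, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(bed))
}

#' Write a genome-by-motif count matrix as TSV with totals
#'
#' Emits one row per genome and one column per motif, plus a `total` column
#' (row sums), a `total` row (column sums) and the grand-total cell. All
#' values are non-negative integers; counts include overlapping occurrences.
#'
#' @param counts Non-empty numeric matrix; rownames are genome ids, colnames
#'   are motifs.
#' @param path Output path.
#' @return Invisibly, the grand total.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(is.matrix(counts), nrow(counts) > 0L, ncol(counts) > 0L)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("genome", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("motif", seq_len(ncol(counts)))
  full <- rbind(cbind(counts, total = rowSums(counts)),
                total = c(colSums(counts), sum(counts)))
  df <- data.frame(genome_id = rownames(full), full, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sum(counts))
}

#' Read back a count table written by [write_count_table()]
#'
#' @param path Path to the TSV.
#' @return List with `counts` (matrix without the totals margin),
#'   `row_totals`, `col_totals`, `grand_total`.
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 3L, names(df)[1] == "genome_id")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$genome_id
  n <- nrow(mat); p <- ncol(mat)
  list(counts = mat[-n, -p, drop = FALSE],
       row_totals = mat[-n, p],
       col_totals = mat[n, -p],
       grand_total = mat[n, p])
}
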
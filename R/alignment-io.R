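#' @importFrom stats coef cor.test lm median nls optim predict sd setNames smooth.spline rnorm runif
#' @importFrom utils read.csv write.csv head
NULL

#' Protein alphabet used for alignment and model bookkeeping
#'
#' The 21-state alphabet: the gap character followed by the twenty
#' proteinogenic amino acids in alphabetical one-letter order. The gap is a
#' modeled state (non-focus rows keep gaps in retained columns), but
#' substitutions to or from the gap state are never proposed as variants.
#'
#' @return Character vector of length 21, gap (`"-"`) first.
#' @export
aa_alphabet <- function() {
  c("-", "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# residues with no single-state interpretation; mapped to gap on read
.nonstandard_residues <- c("B", "Z", "X", "U", "O", "J", "*")

#' Read a multiple sequence alignment and focus-map it
#'
#' Reads FASTA, A2M or Stockholm alignments. Insert states (lowercase
#' residues and `"."` columns in A2M/Stockholm) are removed per sequence so
#' that all rows align on match columns. Columns in which the focus (target)
#' sequence carries a gap are then dropped, so every retained column maps to
#' a 1-based position in the ungapped focus sequence (`column_map`).
#' Non-standard residues (B, Z, X, U, O, J, *) are mapped to the gap state
#' with a message reporting the count.
#'
#' @param path Path to the alignment file.
#' @param format One of `"fasta"`, `"a2m"`, `"stockholm"`.
#' @param focus_id Identifier of the focus sequence (matched against the
#'   full header and its first whitespace-delimited token); must occur
#'   exactly once.
#' @return An object of class `"msa"`: a list with `ids`, `matrix`
#'   (character matrix, rows = sequences, columns = retained alignment
#'   columns), `focus_id`, `column_map` (strictly increasing 1-based focus
#'   positions) and `alphabet`.
#' @export
read_alignment <- function(path, format = c("fasta", "a2m", "stockholm"),
                           focus_id) {
  format <- match.arg(format)
  if (format %in% c("fasta", "a2m")) {
    set <- Biostrings::readBStringSet(path)
    ids <- names(set)
    seqs <- as.character(set)
  } else {
    sto <- .read_stockholm(path)
    ids <- sto$ids
    seqs <- sto$seqs
  }
  if (length(ids) == 0L) stop("alignment file contains no sequences")
  tokens <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  hit <- which(ids == focus_id | tokens == focus_id)
  if (length(hit) == 0L) stop("focus_id '", focus_id, "' not found in alignment")
  if (length(hit) > 1L) stop("focus_id '", focus_id, "' occurs more than once")

  rows <- strsplit(seqs, "", fixed = TRUE)
  if (format %in% c("a2m", "stockholm")) {
    # insert states: lowercase letters and "." — removed per sequence
    rows <- lapply(rows, function(r) r[!(r %in% c(".") | r %in% letters)])
  } else {
    rows <- lapply(rows, function(r) {
      r[r == "."] <- "-"
      toupper(r)
    })
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: row lengths differ (", paste(range(lens), collapse = "-"), ")")
  mat <- do.call(rbind, rows)
  dimnames(mat) <- NULL
  mat[] <- toupper(mat)

  n_odd <- sum(mat %in% .nonstandard_residues)
  if (n_odd > 0L) {
    mat[mat %in% .nonstandard_residues] <- "-"
    message("mapped ", n_odd, " non-standard residue(s) to gap")
  }
  bad <- setdiff(unique(as.vector(mat)), aa_alphabet())
  if (length(bad) > 0L)
    stop("unknown residue characters: ", paste(bad, collapse = ", "))

  focus_row <- mat[hit, ]
  keep <- focus_row != "-"
  mat <- mat[, keep, drop = FALSE]
  column_map <- seq_len(sum(keep))

  structure(list(ids = tokens, matrix = mat, focus_id = tokens[hit],
                 column_map = column_map, alphabet = aa_alphabet()),
            class = "msa")
}

.read_stockholm <- function(path) {
  lines <- readLines(path)
  acc <- list()
  order_ids <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#") || startsWith(ln, "//")) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2L) stop("malformed Stockholm line: ", ln)
    id <- parts[1]
    if (is.null(acc[[id]])) {
      acc[[id]] <- parts[2]
      order_ids <- c(order_ids, id)
    } else {
      acc[[id]] <- paste0(acc[[id]], parts[2])
    }
  }
  list(ids = order_ids, seqs = unlist(acc[order_ids], use.names = FALSE))
}

#' Construct an alignment object from a character matrix
#'
#' Low-level constructor used by the synthetic generators and tests.
#'
#' @param mat Character matrix (rows = sequences).
#' @param ids Sequence identifiers (default `seq_1 ...`).
#' @param focus_id Identifier of the focus row (default the first row).
#' @param column_map 1-based focus positions of the columns (default `1:L`).
#' @param alphabet State alphabet, gap first (default [aa_alphabet()]).
#' @return An `"msa"` object.
#' @export
msa_from_matrix <- function(mat, ids = NULL, focus_id = NULL,
                            column_map = NULL, alphabet = aa_alphabet()) {
  if (is.null(ids)) ids <- paste0("seq_", seq_len(nrow(mat)))
  if (is.null(focus_id)) focus_id <- ids[1]
  if (is.null(column_map)) column_map <- seq_len(ncol(mat))
  stopifnot(length(ids) == nrow(mat), length(column_map) == ncol(mat),
            focus_id %in% ids)
  structure(list(ids = ids, matrix = mat, focus_id = focus_id,
                 column_map = as.integer(column_map), alphabet = alphabet),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", nrow(x$matrix), " sequences x ",
      ncol(x$matrix), " columns\n", sep = "")
  cat("focus: ", x$focus_id, " (positions ",
      if (length(x$column_map)) paste0(min(x$column_map), "-", max(x$column_map)) else "none",
      ")\n", sep = "")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param aln An `"msa"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$matrix, 1, paste0, collapse = "")
  set <- Biostrings::BStringSet(setNames(seqs, aln$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Filter an alignment by gap content
#'
#' Rows (sequences) with a gap fraction above `max_seq_gap` are removed
#' first; then columns with a gap fraction above `max_col_gap`, computed
#' over the surviving rows, are removed. The focus row is never removed and
#' `column_map` is updated for dropped columns. The per-sequence filter
#' report is attached as attribute `"filter_report"` (see
#' [filter_report()]).
#'
#' @param aln An `"msa"` object.
#' @param max_seq_gap Maximum tolerated per-sequence gap fraction
#'   (default 0.5).
#' @param max_col_gap Maximum tolerated per-column gap fraction
#'   (default 0.3).
#' @return The filtered `"msa"` object.
#' @export
filter_alignment <- function(aln, max_seq_gap = 0.5, max_col_gap = 0.3) {
  stopifnot(inherits(aln, "msa"),
            max_seq_gap >= 0, max_seq_gap <= 1,
            max_col_gap >= 0, max_col_gap <= 1)
  mat <- aln$matrix
  seq_gap <- rowMeans(mat == "-")
  keep_row <- seq_gap <= max_seq_gap
  focus_idx <- match(aln$focus_id, aln$ids)
  if (!keep_row[focus_idx])
    stop("focus sequence '", aln$focus_id, "' would be removed by the sequence gap filter")
  report <- data.frame(sequence_id = aln$ids, gap_fraction = seq_gap,
                       kept = keep_row, stringsAsFactors = FALSE)
  if (sum(keep_row) < 2L && nrow(mat) > 1L)
    stop("sequence gap filter removed all non-focus rows")
  mat <- mat[keep_row, , drop = FALSE]
  ids <- aln$ids[keep_row]

  col_gap <- colMeans(mat == "-")
  keep_col <- col_gap <= max_col_gap
  out <- structure(list(ids = ids, matrix = mat[, keep_col, drop = FALSE],
                        focus_id = aln$focus_id,
                        column_map = aln$column_map[keep_col],
                        alphabet = aln$alphabet),
                   class = "msa")
  attr(out, "filter_report") <- report
  out
}

#' Per-sequence gap-filter report
#'
#' @param aln An alignment returned by [filter_alignment()].
#' @return Data frame with columns `sequence_id`, `gap_fraction`, `kept`.
#' @export
filter_report <- function(aln) {
  rep <- attr(aln, "filter_report")
  if (is.null(rep)) stop("alignment carries no filter report; run filter_alignment() first")
  rep
}
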
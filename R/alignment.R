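#' Alignment objects
#'
#' An `evh_alignment` holds aligned homolog rows over the focus columns of a
#' protein family, the original column indices those focus columns came from,
#' and the row index of the designated target sequence. All rows have equal
#' length and are uppercase; ambiguous residues are mapped to the gap symbol.
#'
#' @param ids character vector of record identifiers.
#' @param rows character vector of aligned rows (equal lengths).
#' @param target_index row index of the target sequence.
#' @param focus_columns original (1-based) column indices retained; defaults
#'   to `1:L`.
#' @param alphabet ordered symbol set, see [aa_alphabet()].
#' @return an object of class `evh_alignment`.
#' @export
new_alignment <- function(ids, rows, target_index = 1L,
                          focus_columns = NULL, alphabet = aa_alphabet()) {
  stopifnot(length(ids) == length(rows), length(rows) >= 1L)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- ids[which(widths != widths[1])[1]]
    stop("ragged alignment: record '", bad, "' has a different length", call. = FALSE)
  }
  rows <- unname(toupper(rows)); ids <- unname(ids)
  # map ambiguous residues to gap
  for (u in UNKNOWN_RESIDUES) rows <- gsub(u, GAP, rows, fixed = TRUE)
  target_index <- as.integer(target_index)
  if (target_index < 1L || target_index > length(rows))
    stop("target_index out of range", call. = FALSE)
  if (is.null(focus_columns)) focus_columns <- seq_len(widths[1])
  focus_columns <- as.integer(focus_columns)
  if (length(focus_columns) != widths[1] || is.unsorted(focus_columns, strictly = TRUE))
    stop("focus_columns must be strictly increasing and match the row width", call. = FALSE)
  bad_chars <- setdiff(unique(strsplit(paste(rows, collapse = ""), "")[[1]]), alphabet)
  if (length(bad_chars) > 0)
    stop("rows contain symbols outside the alphabet: ",
         paste(bad_chars, collapse = ", "), call. = FALSE)
  structure(
    list(ids = as.character(ids), rows = rows, target_index = target_index,
         focus_columns = focus_columns, alphabet = alphabet),
    class = "evh_alignment"
  )
}

#' @export
print.evh_alignment <- function(x, ...) {
  cat("<evh_alignment> ", length(x$rows), " records x ",
      length(x$focus_columns), " focus columns\n", sep = "")
  cat("  target: ", x$ids[x$target_index], " (row ", x$target_index, ")\n", sep = "")
  invisible(x)
}

#' @export
length.evh_alignment <- function(x) length(x$rows)

# n x L character matrix of the alignment
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA, A2M or Stockholm files. In A2M, lowercase letters and
#' `.` mark insert states relative to the alignment columns; insert columns
#' are removed and the remaining (match) columns become the focus columns.
#' Format `"auto"` dispatches on content: Stockholm by its header, A2M when
#' lowercase/`.` characters are present, plain aligned FASTA otherwise.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"fasta"`, `"a2m"`, `"stockholm"`.
#' @param target_id id of the target record (default: first record).
#' @return an [new_alignment()] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "a2m", "stockholm"),
                           target_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "stockholm") {
    rec <- read_stockholm_records(path)
  } else {
    aa <- Biostrings::readBStringSet(path)  # BStringSet keeps case for A2M
    if (length(aa) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    rec <- list(ids = sub("\\s.*$", "", names(aa)), rows = as.character(aa))
  }
  rows <- rec$rows
  is_a2m <- format == "a2m" ||
    (format == "fasta" && any(grepl("[a-z.]", rows)))
  if (is_a2m) {
    # match columns: positions that are uppercase or '-' in every row; inserts
    # (lowercase / '.') are stripped row-wise
    rows <- vapply(rows, function(r) {
      ch <- strsplit(r, "", fixed = TRUE)[[1]]
      paste(ch[!(ch %in% c(".", letters))], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- rec$ids[which(widths != widths[1])[1]]
    stop("ragged alignment: record '", bad, "' has a different length", call. = FALSE)
  }
  ti <- 1L
  if (!is.null(target_id)) {
    ti <- match(target_id, rec$ids)
    if (is.na(ti)) stop("target_id '", target_id, "' not found", call. = FALSE)
  }
  new_alignment(rec$ids, rows, target_index = ti)
}

read_stockholm_records <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  seqs <- list()
  for (ln in lines) {
    if (grepl("^#", ln) || grepl("^//", ln) || !nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2L) stop("malformed Stockholm line: ", ln, call. = FALSE)
    id <- parts[1]
    seqs[[id]] <- paste0(if (is.null(seqs[[id]])) "" else seqs[[id]], parts[2])
  }
  if (length(seqs) == 0L) stop("no sequences in Stockholm file: ", path, call. = FALSE)
  list(ids = names(seqs), rows = unname(unlist(seqs)))
}

#' Write an alignment
#'
#' @param aln an [new_alignment()] object.
#' @param path output path.
#' @param format `"fasta"` or `"stockholm"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", aln$ids), aln$rows)), path)
  } else {
    w <- max(nchar(aln$ids))
    writeLines(c("# STOCKHOLM 1.0",
                 sprintf("%-*s %s", w, aln$ids, aln$rows),
                 "//"), path)
  }
  invisible(path)
}

#' Filter an alignment by fragment coverage and column gap fraction
#'
#' First drops fragment records whose non-gap overlap with the target's
#' non-gap columns is below `min_coverage` of the target's non-gap length;
#' then drops columns whose gap fraction over the remaining records exceeds
#' `max_col_gap`. The target record is never dropped. Idempotent at fixed
#' thresholds.
#'
#' @param aln an [new_alignment()].
#' @param max_col_gap drop columns with gap fraction strictly greater than
#'   this (default 0.30).
#' @param min_coverage drop records covering strictly less than this fraction
#'   of the target's non-gap positions (default 0.50).
#' @return a filtered `evh_alignment`; `focus_columns` tracks the surviving
#'   original column indices.
#' @export
filter_alignment <- function(aln, max_col_gap = 0.30, min_coverage = 0.50) {
  stopifnot(inherits(aln, "evh_alignment"),
            max_col_gap > 0, max_col_gap < 1, min_coverage > 0, min_coverage < 1)
  m <- aln_matrix(aln)
  tgt_nongap <- m[aln$target_index, ] != GAP
  n_tgt <- sum(tgt_nongap)
  if (n_tgt == 0L) stop("target sequence is all gaps", call. = FALSE)
  coverage <- rowSums(m[, tgt_nongap, drop = FALSE] != GAP) / n_tgt
  keep_rec <- coverage >= min_coverage
  keep_rec[aln$target_index] <- TRUE
  if (sum(keep_rec) <= 1L)
    stop("coverage filter removed every non-target record; lower min_coverage",
         call. = FALSE)
  m2 <- m[keep_rec, , drop = FALSE]
  gap_frac <- colMeans(m2 == GAP)
  keep_col <- gap_frac <= max_col_gap
  if (!any(keep_col)) stop("gap filter removed every column", call. = FALSE)
  rows <- apply(m2[, keep_col, drop = FALSE], 1, paste, collapse = "")
  new_alignment(aln$ids[keep_rec], rows,
                target_index = match(aln$target_index, which(keep_rec)),
                focus_columns = aln$focus_columns[keep_col],
                alphabet = aln$alphabet)
}

#' Normalized Hamming distance between aligned rows
#'
#' Fraction of focus positions at which two aligned rows differ. A gap versus
#' a residue counts as a mismatch; gap versus gap counts as a match, so the
#' distance is a metric over aligned rows and `1 - D` is the usual percent
#' identity.
#'
#' @param a,b character strings (aligned rows) or encoded integer vectors of
#'   equal length.
#' @return a fraction in `[0, 1]`.
#' @export
#' @examples
#' normalized_hamming("AAAA", "AAAC")  # 0.25
#' normalized_hamming("AA-A", "AAAA")  # 0.25: gap vs residue mismatches
normalized_hamming <- function(a, b) {
  if (is.character(a) && length(a) == 1L)
    a <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  if (is.character(b) && length(b) == 1L)
    b <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("sequences have different lengths (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  mean(a != b)
}

#' Redundancy reweighting of alignment records
#'
#' Each record's weight is the reciprocal of the number of records (itself
#' included) within normalized Hamming distance `theta` of it; the effective
#' number of sequences `n_eff` is the sum of weights. This is the standard
#' uniqueness reweighting used in direct coupling analysis, with the
#' conventional cutoff `theta = 0.2`.
#'
#' @param aln an [new_alignment()], typically after [filter_alignment()].
#' @param theta distance cutoff; a neighbour is a record at distance
#'   strictly less than `theta`.
#' @return an object of class `evh_weights` with fields `weights`, `theta`,
#'   `n_eff`, `ids`.
#' @export
sequence_weights <- function(aln, theta = 0.2) {
  stopifnot(inherits(aln, "evh_alignment"), theta > 0, theta <= 1)
  X <- encode_rows(aln$rows, aln$alphabet)
  w <- cpp_sequence_weights(X, theta)
  structure(list(weights = w, theta = theta, n_eff = sum(w), ids = aln$ids),
            class = "evh_weights")
}

#' @export
print.evh_weights <- function(x, ...) {
  cat("<evh_weights> ", length(x$weights), " records, theta = ", x$theta,
      ", n_eff = ", format(x$n_eff, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.evh_weights <- function(x, ...) {
  tibble::tibble(id = x$ids, weight = x$weights)
}

#' Write per-record weights as TSV
#' @param w an `evh_weights` object.
#' @param path output path.
#' @export
write_weights <- function(w, path) {
  utils::write.table(tidy(w), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reweighted consensus sequence
#'
#' The sequence formed by the non-gap symbol with the highest redundancy-
#' weighted frequency at each focus column. Ties are broken by alphabet
#' order (first symbol in the alignment's alphabet wins).
#'
#' @param aln an [new_alignment()].
#' @param weights an `evh_weights` from [sequence_weights()]; unit weights
#'   if omitted.
#' @return a character string of length `L`.
#' @export
reweighted_consensus <- function(aln, weights = NULL) {
  stopifnot(inherits(aln, "evh_alignment"))
  w <- if (is.null(weights)) rep(1, length(aln$rows)) else weights$weights
  if (length(w) != length(aln$rows))
    stop("weights do not align 1:1 with records", call. = FALSE)
  m <- aln_matrix(aln)
  ab <- setdiff(aln$alphabet, GAP)
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    keep <- col != GAP
    if (!any(keep))
      stop("column ", j, " contains only gaps; filter the alignment first",
           call. = FALSE)
    freq <- vapply(ab, function(a) sum(w[keep][col[keep] == a]), numeric(1))
    ab[which.max(freq)]  # which.max takes the first maximum: alphabet-order tie break
  }, character(1))
  paste(cons, collapse = "")
}
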
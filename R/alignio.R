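# Alignment carrier shared by the probing (ac4C-seq) and footprint stages.
#
# An alignment set is a data.frame with one row per read:
#   read_id, ref_id, start (1-based leftmost reference position), aligned
# where `aligned` holds one character per consumed reference position
# (A/C/G/T, or "-" for a deletion). Insertions consume no reference
# position and are dropped; soft-clipped bases are ignored for pileup
# purposes. Only single-end, forward-strand alignments are handled.

.new_alignment_set <- function(df, n_excluded = 0L) {
  rownames(df) <- NULL
  structure(df, class = c("alignment_set", "data.frame"),
            n_excluded = n_excluded)
}

#' Construct an alignment set from vectors
#'
#' @param read_id,ref_id Character vectors.
#' @param start 1-based leftmost aligned reference position.
#' @param aligned Per-reference-position base string (`-` marks a deletion);
#'   its width is the reference span of the read.
#' @return An `alignment_set` (a data.frame subclass) with attribute
#'   `n_excluded` (reads dropped at parse time).
#' @export
alignment_set <- function(read_id, ref_id, start, aligned) {
  stopifnot(length(read_id) == length(ref_id),
            length(ref_id) == length(start),
            length(start) == length(aligned))
  aligned <- normalize_seq(aligned)
  if (length(aligned) > 0) .check_alphabet(aligned, extra = "-", what = "aligned base")
  if (any(start < 1)) stop("alignment start must be >= 1")
  .new_alignment_set(data.frame(read_id = as.character(read_id),
                                ref_id = as.character(ref_id),
                                start = as.integer(start),
                                aligned = aligned))
}

#' Number of reads excluded while reading alignments
#' @param aln An `alignment_set`.
#' @return Integer count of reads dropped (e.g. mapped to unknown references).
#' @export
n_excluded <- function(aln) {
  v <- attr(aln, "n_excluded")
  if (is.null(v)) 0L else v
}

# Expand one CIGAR + SEQ into the per-reference-position base string.
# Supported ops: M/=/X (consume both), I/S (consume read only), D (consumes
# reference, emits "-"), H (consumes neither). Anything else errors.
.cigar_to_aligned <- function(cigar, seq) {
  ops <- gregexpr("[0-9]+[A-Z=]", cigar)[[1]]
  if (ops[1] == -1L) stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  out <- character(0)
  qpos <- 1L
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      out <- c(out, substr(seq, qpos, qpos + n[i] - 1L))
      qpos <- qpos + n[i]
    } else if (op[i] %in% c("I", "S")) {
      qpos <- qpos + n[i]
    } else if (op[i] == "D") {
      out <- c(out, strrep("-", n[i]))
    } else if (op[i] == "H") {
      # clipped bases absent from SEQ; nothing to do
    } else {
      stop("unsupported CIGAR op '", op[i], "' in ", cigar)
    }
  }
  paste(out, collapse = "")
}

#' Read alignments (SAM subset or TSV dialect)
#'
#' Reads a text SAM file (header optional; M/=/X/I/D/S/H CIGAR ops;
#' single-end forward-strand records) or the package's tabular dialect
#' (header `read_id ref_id start aligned`, tab-separated, `aligned` as
#' stored by [alignment_set()]). Reads mapped to references absent from
#' `refs` are excluded and counted in the `n_excluded` attribute.
#'
#' @param path Input path.
#' @param refs A [reference_set()] the alignments must refer to.
#' @param format `"auto"` (by extension/content), `"sam"` or `"tsv"`.
#' @return An `alignment_set`.
#' @export
read_alignments <- function(path, refs, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(refs, "ReferenceSet"))
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE) ||
                  any(startsWith(lines, "@")))
      "sam"
    else if (length(lines) > 0 && startsWith(lines[1], "read_id\t"))
      "tsv"
    else "sam"
  }
  keep <- !startsWith(lines, "@") & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  if (format == "tsv") {
    if (length(body) == 0) return(alignment_set(character(), character(),
                                                integer(), character()))
    hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    need <- c("read_id", "ref_id", "start", "aligned")
    if (!all(need %in% hdr))
      stop("TSV alignment file must have columns: ", paste(need, collapse = ", "))
    df <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                            colClasses = "character")
    read_id <- df$read_id; rname <- df$ref_id
    pos <- suppressWarnings(as.integer(df$start)); aligned <- df$aligned
    if (anyNA(pos)) stop("malformed line ", lineno[which(is.na(pos)) + 1L],
                         ": non-integer start")
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11))
      stop("malformed line ", lineno[which(nf < 11)[1]],
           ": expected >= 11 SAM fields, got ", nf[which(nf < 11)[1]])
    read_id <- vapply(fields, `[[`, "", 1L)
    rname <- vapply(fields, `[[`, "", 3L)
    pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
    cigar <- vapply(fields, `[[`, "", 6L)
    seq <- vapply(fields, `[[`, "", 10L)
    if (anyNA(pos))
      stop("malformed line ", lineno[which(is.na(pos))[1]], ": bad POS field")
    aligned <- rep(NA_character_, length(body))
    for (i in seq_along(body)) {
      if (rname[i] == "*" || cigar[i] == "*") next
      aligned[i] <- tryCatch(.cigar_to_aligned(cigar[i], seq[i]),
                             error = function(e)
                               stop("malformed line ", lineno[i], ": ",
                                    conditionMessage(e), call. = FALSE))
    }
    unmapped <- is.na(aligned)
    read_id <- read_id[!unmapped]; rname <- rname[!unmapped]
    pos <- pos[!unmapped]; aligned <- aligned[!unmapped]
  }
  known <- rname %in% names(refs)
  n_bad <- sum(!known)
  if (n_bad > 0)
    message(n_bad, " read(s) mapped to unknown reference(s) excluded")
  out <- alignment_set(read_id[known], rname[known], pos[known], aligned[known])
  # reject reads running off the reference end
  len <- ref_lengths(refs)[out$ref_id]
  over <- out$start + nchar(out$aligned) - 1L > len
  if (any(over)) {
    n_bad <- n_bad + sum(over)
    message(sum(over), " read(s) extending past the reference end excluded")
    out <- out[!over, , drop = FALSE]
  }
  .new_alignment_set(as.data.frame(out), n_excluded = as.integer(n_bad))
}

#' Write an alignment set to the TSV dialect
#' @param aln An `alignment_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignments <- function(aln, path) {
  utils::write.table(as.data.frame(aln)[, c("read_id", "ref_id", "start", "aligned")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
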
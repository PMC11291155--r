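# Reference sequence container. Coordinates are 1-based and inclusive on the
# mature reference sequence everywhere: "C12" means the 12th nucleotide.

#' Create a reference sequence set
#'
#' Container for named nucleotide sequences (mature tRNAs or coding
#' sequences) with optional per-site modification annotations. Sequences
#' are stored on the DNA alphabet (U converted to T, case-folded).
#'
#' @param sequences Named character vector of sequences. Names are the
#'   reference ids and must be unique; sequences must be non-empty.
#' @param annotations Optional data.frame with columns `ref_id`,
#'   `position` (1-based) and `label`; every position must lie within its
#'   reference.
#' @return An object of class `ReferenceSet` with elements `seq` (named
#'   character vector) and `annotations` (data.frame).
#' @export
reference_set <- function(sequences = character(), annotations = NULL) {
  ids <- names(sequences)
  if (length(sequences) > 0 && (is.null(ids) || any(ids == "")))
    stop("all sequences must be named")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate reference id(s): ", paste(unique(dup), collapse = ", "))
  sequences <- normalize_seq(sequences)
  if (any(nchar(sequences) == 0))
    stop("empty sequence for id(s): ",
         paste(ids[nchar(sequences) == 0], collapse = ", "))
  if (length(sequences) > 0) .check_alphabet(sequences)
  if (is.null(annotations)) {
    annotations <- data.frame(ref_id = character(), position = integer(),
                              label = character())
  } else {
    stopifnot(all(c("ref_id", "position", "label") %in% names(annotations)))
    annotations <- as.data.frame(annotations)[, c("ref_id", "position", "label")]
    bad <- !(annotations$ref_id %in% ids)
    if (any(bad))
      stop("annotation for unknown reference: ",
           paste(unique(annotations$ref_id[bad]), collapse = ", "))
    len <- nchar(sequences)[match(annotations$ref_id, ids)]
    out <- annotations$position < 1 | annotations$position > len
    if (any(out)) stop("annotation position outside reference")
  }
  structure(list(seq = sequences, annotations = annotations),
            class = "ReferenceSet")
}

#' @export
length.ReferenceSet <- function(x) length(x$seq)

#' @export
names.ReferenceSet <- function(x) names(x$seq)

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet with", length(x), "sequence(s)")
  if (length(x) > 0)
    cat("; lengths", min(nchar(x$seq)), "-", max(nchar(x$seq)))
  if (nrow(x$annotations) > 0)
    cat(";", nrow(x$annotations), "annotation(s)")
  cat("\n")
  invisible(x)
}

#' Sequence lengths of a ReferenceSet
#' @param refs A [reference_set()].
#' @return Named integer vector of sequence lengths.
#' @export
ref_lengths <- function(refs) {
  stopifnot(inherits(refs, "ReferenceSet"))
  stats::setNames(nchar(refs$seq), names(refs$seq))
}

#' Read a FASTA file into a ReferenceSet
#'
#' Ids are the first whitespace-delimited token of each header. U is
#' converted to T and sequences are upper-cased. An empty file yields an
#' empty ReferenceSet; duplicate ids are an error naming the id.
#'
#' @param path Path to a FASTA file.
#' @return A [reference_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(trimws(lines) == ""))
    return(reference_set())
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- stats::setNames(as.character(x), ids)
  reference_set(seqs)
}

#' Write a ReferenceSet to FASTA
#' @param refs A [reference_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(refs, path) {
  stopifnot(inherits(refs, "ReferenceSet"))
  writeLines(rbind(paste0(">", names(refs)), unname(refs$seq)), path)
  invisible(path)
}
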
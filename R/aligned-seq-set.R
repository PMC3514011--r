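#' Aligned sequence sets
#'
#' An `aligned_seq_set` holds equal-length nucleotide sequences with unique
#' labels and an optional population assignment per sequence. It is the unit
#' on which all sequence statistics in the package operate.
#'
#' @param sequences Character vector of nucleotide sequences (upper- or
#'   lower-case; IUPAC ambiguity codes, `N` and the gap symbol `-` are
#'   accepted). All must have the same number of characters.
#' @param labels Character vector of unique sequence labels. Defaults to
#'   `seq1`, `seq2`, ...
#' @param populations Character vector assigning each sequence to a
#'   population; recycled if length 1. Defaults to `"unassigned"`.
#'
#' @return An object of class `aligned_seq_set`: a list with elements
#'   `labels`, `populations`, `sequences` (character vectors of equal length)
#'   and `length` (alignment columns).
#' @export
aligned_seq_set <- function(sequences, labels = NULL, populations = "unassigned") {
  if (length(sequences) == 0L) {
    stop("empty input: no sequences supplied", call. = FALSE)
  }
  sequences <- toupper(as.character(sequences))
  if (is.null(labels)) labels <- paste0("seq", seq_along(sequences))
  labels <- as.character(labels)
  if (length(labels) != length(sequences)) {
    stop("labels and sequences differ in length", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate sequence labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  populations <- rep_len(as.character(populations), length(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- labels[lens != stats::median(lens)]
    stop("alignment error: sequences of unequal length (",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  allowed <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-", "?")
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  if (length(setdiff(chars, allowed)) > 0L) {
    stop("invalid characters in sequences: ",
         paste(setdiff(chars, allowed), collapse = ", "), call. = FALSE)
  }
  structure(
    list(labels = labels, populations = populations,
         sequences = sequences, length = unname(lens[1L])),
    class = "aligned_seq_set"
  )
}

#' @export
print.aligned_seq_set <- function(x, ...) {
  cat("Aligned sequence set: ", length(x$labels), " sequences x ",
      x$length, " columns\n", sep = "")
  cat("Populations: ", paste(sort(unique(x$populations)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.aligned_seq_set <- function(x) length(x$labels)

#' Convert an alignment to a character matrix
#'
#' @param x An `aligned_seq_set`.
#' @return A character matrix, one row per sequence, with row names the
#'   sequence labels.
#' @export
as_seq_matrix <- function(x) {
  stopifnot(inherits(x, "aligned_seq_set"))
  m <- do.call(rbind, strsplit(x$sequences, ""))
  rownames(m) <- x$labels
  m
}

#' Read an aligned FASTA file
#'
#' Sequences are upper-cased and validated to share one alignment length.
#'
#' @param path Path to a FASTA file.
#' @param metadata Optional named character vector or two-column data frame
#'   (`label`, `population`) mapping sequence labels to populations; labels
#'   absent from the map default to `"unassigned"`.
#' @return An [aligned_seq_set()].
#' @export
read_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- tryCatch(
    suppressWarnings(ape::read.dna(path, format = "fasta",
                                   as.character = TRUE,
                                   as.matrix = FALSE)),
    error = function(e) stop("could not parse FASTA: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (length(dna) == 0L) stop("empty input: no sequences in ", path,
                              call. = FALSE)
  seqs <- vapply(dna, function(s) paste(toupper(s), collapse = ""), "")
  labs <- names(dna)
  pops <- rep("unassigned", length(labs))
  if (!is.null(metadata)) {
    if (is.data.frame(metadata)) {
      metadata <- stats::setNames(as.character(metadata[[2L]]),
                                  as.character(metadata[[1L]]))
    }
    hit <- labs %in% names(metadata)
    pops[hit] <- unname(metadata[labs[hit]])
  }
  aligned_seq_set(seqs, labels = labs, populations = pops)
}

#' Write an alignment as FASTA
#'
#' Sequences are wrapped at 70 columns.
#'
#' @param x An `aligned_seq_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "aligned_seq_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$labels)) {
    writeLines(paste0(">", x$labels[i]), con)
    s <- x$sequences[i]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Trim an alignment to a column window
#'
#' Columns are addressed 0-based with a half-open window `[start, end)`, so
#' `trim_to_window(x, 0, 489)` keeps the first 489 alignment columns. This
#' mirrors how fixed-length barcode windows (e.g. 489 or 388 nucleotides) are
#' specified throughout the package.
#'
#' @param x An `aligned_seq_set`.
#' @param start First column to keep (0-based).
#' @param end One past the last column to keep.
#' @return A trimmed `aligned_seq_set` of length `end - start`.
#' @export
trim_to_window <- function(x, start, end) {
  stopifnot(inherits(x, "aligned_seq_set"))
  if (!(start >= 0 && start < end && end <= x$length)) {
    stop("window [", start, ", ", end, ") outside alignment of length ",
         x$length, call. = FALSE)
  }
  seqs <- substring(x$sequences, start + 1L, end)
  aligned_seq_set(seqs, labels = x$labels, populations = x$populations)
}

#' Base composition of an alignment
#'
#' Fractions of A, C, G and T over unambiguous calls only; ambiguity codes,
#' `N` and gaps are ignored.
#'
#' @param x An `aligned_seq_set`.
#' @return Named numeric vector with elements `A`, `C`, `G`, `T` summing
#'   to 1.
#' @export
base_composition <- function(x) {
  stopifnot(inherits(x, "aligned_seq_set"))
  chars <- strsplit(paste(x$sequences, collapse = ""), "")[[1]]
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), 0)
  if (sum(counts) == 0) {
    stop("no unambiguous bases in alignment", call. = FALSE)
  }
  counts / sum(counts)
}

# characters treated as unambiguous nucleotide calls throughout the package
.unambiguous <- c("A", "C", "G", "T")

is_ambiguous_char <- function(ch) !(ch %in% .unambiguous)
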
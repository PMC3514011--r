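#' Collapse aligned sequences to haplotypes
#'
#' Identical sequences are pooled into haplotypes with per-population counts.
#' Under the default `"mask"` policy, every alignment column containing an
#' ambiguity code, `N` or a gap in *any* sequence is removed set-wide before
#' identity comparison, so the haplotype sequences returned are over the
#' retained (fully resolved) columns; the retained column indices (1-based)
#' are stored in the `retained_columns` attribute. Under `"strict"` any
#' ambiguity symbol is an error.
#'
#' @param x An [aligned_seq_set()].
#' @param ambiguity_policy `"mask"` (default) or `"strict"`.
#' @return A `haplotype_table`: a data frame with columns `haplotype_id`,
#'   `sequence`, `total_count`, then one count column per population.
#'   Attribute `assignment` maps each input label to its haplotype id.
#' @export
collapse_haplotypes <- function(x, ambiguity_policy = c("mask", "strict")) {
  stopifnot(inherits(x, "aligned_seq_set"))
  ambiguity_policy <- match.arg(ambiguity_policy)
  m <- as_seq_matrix(x)
  amb <- !(m %in% .unambiguous)
  dim(amb) <- dim(m)
  if (ambiguity_policy == "strict" && any(amb)) {
    pos <- which(apply(amb, 2L, any))
    stop("ambiguous characters at alignment columns: ",
         paste(pos, collapse = ", "), call. = FALSE)
  }
  keep <- !apply(amb, 2L, any)
  if (!any(keep)) stop("no unambiguous columns left after masking",
                       call. = FALSE)
  core <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  uniq <- unique(core)
  # order haplotypes by decreasing total count, ties by first appearance
  tot <- vapply(uniq, function(s) sum(core == s), 0L)
  uniq <- uniq[order(-tot, match(uniq, core))]
  ids <- paste0("H", seq_along(uniq))
  assignment <- stats::setNames(ids[match(core, uniq)], x$labels)
  pops <- sort(unique(x$populations))
  counts <- matrix(0L, nrow = length(uniq), ncol = length(pops))
  for (k in seq_along(pops)) {
    counts[, k] <- vapply(uniq, function(s) {
      sum(core == s & x$populations == pops[k])
    }, 0L)
  }
  out <- data.frame(
    haplotype_id = ids,
    sequence = uniq,
    total_count = as.integer(rowSums(counts)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  cnt <- as.data.frame(counts, row.names = NULL)
  names(cnt) <- pops
  out <- cbind(out, cnt)
  rownames(out) <- NULL
  attr(out, "retained_columns") <- which(keep)
  attr(out, "assignment") <- assignment
  class(out) <- c("haplotype_table", "data.frame")
  out
}

#' Expand a haplotype table back to sequences
#'
#' Inverse of [collapse_haplotypes()] up to labels: each haplotype is
#' repeated `total_count` times, with populations taken from the per-
#' population count columns.
#'
#' @param haps A `haplotype_table`.
#' @return An [aligned_seq_set()].
#' @export
expand_haplotypes <- function(haps) {
  stopifnot(inherits(haps, "haplotype_table"))
  pops <- setdiff(names(haps), c("haplotype_id", "sequence", "total_count"))
  seqs <- character(0); popv <- character(0)
  for (i in seq_len(nrow(haps))) {
    for (p in pops) {
      k <- haps[[p]][i]
      if (k > 0L) {
        seqs <- c(seqs, rep(haps$sequence[i], k))
        popv <- c(popv, rep(p, k))
      }
    }
  }
  aligned_seq_set(seqs, populations = popv)
}

#' Write / read a haplotype table as CSV
#'
#' @param haps A `haplotype_table`.
#' @param path CSV path.
#' @return `path` invisibly, or the re-read `haplotype_table`.
#' @export
write_haplotype_table <- function(haps, path) {
  utils::write.csv(as.data.frame(haps), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotype_table
#' @export
read_haplotype_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("haplotype_table", "data.frame")
  out
}
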
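#' Symmetric distance matrices
#'
#' Lightweight container for labelled symmetric distance matrices with a
#' zero diagonal, used for sequence (K2P), geographic, temperature and
#' clade-indicator distances.
#'
#' @param values Square numeric matrix.
#' @param labels Optional item labels; default taken from `dimnames`.
#' @return A `dist_matrix` (numeric matrix with class attribute).
#' @export
dist_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix not square", call. = FALSE)
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("item", seq_len(nrow(values)))
  if (length(labels) != nrow(values)) stop("labels/dimension mismatch",
                                           call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite distances", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12) stop("matrix not symmetric",
                                                 call. = FALSE)
  if (any(diag(values) != 0)) stop("diagonal must be exactly zero",
                                   call. = FALSE)
  if (any(values < 0)) stop("negative distances", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Distance matrix over", nrow(x), "items\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' Strict lower-triangle vector of a distance matrix
#'
#' @param x A `dist_matrix` or square matrix.
#' @return Numeric vector in column-major lower-triangle order.
#' @export
lower_triangle <- function(x) {
  x <- as.matrix(x)
  x[lower.tri(x)]
}

#' Write / read a distance matrix as square CSV
#'
#' The CSV carries labels as header row and first column. `read_dist_matrix`
#' also accepts PHYLIP square format (first line the item count, then one
#' row per item starting with its label).
#'
#' @param x A `dist_matrix`.
#' @param path File path.
#' @return `path` invisibly, or a `dist_matrix`.
#' @export
write_dist_matrix <- function(x, path) {
  df <- data.frame(label = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*[0-9]+\\s*$", first)) {
    n <- as.integer(trimws(first))
    body <- utils::read.table(path, skip = 1L, header = FALSE,
                              stringsAsFactors = FALSE)
    labs <- as.character(body[[1L]])
    vals <- as.matrix(body[, -1L, drop = FALSE])
    if (nrow(vals) != n || ncol(vals) != n) {
      stop("PHYLIP matrix dimensions disagree with header", call. = FALSE)
    }
  } else {
    body <- utils::read.csv(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    labs <- as.character(body[[1L]])
    vals <- as.matrix(body[, -1L, drop = FALSE])
  }
  storage.mode(vals) <- "double"
  # tolerate tiny asymmetries from printed precision
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 0
  dist_matrix(vals, labels = labs)
}
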
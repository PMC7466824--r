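#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of column (sample) identifiers and a first column of
#' row (gene) identifiers. The separator is inferred from the file extension
#' (`.csv` is comma, anything else tab) unless given explicitly.
#'
#' @param file Path to the matrix file.
#' @param sep Field separator; `NULL` to infer from the extension.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(file, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Binarize a numeric matrix at an expression cutoff
#'
#' A cell becomes 1 when its value is strictly greater than `threshold`
#' (values equal to the cutoff go to 0), mirroring the usual
#' "expressed above 0.5 TPM" convention for RNA-seq abundance matrices.
#'
#' @param m Numeric matrix with unique row and column names.
#' @param threshold Finite expression cutoff; default 0.5.
#' @return Integer 0/1 matrix with the same dimnames.
#' @examples
#' binarize(matrix(c(0.6, 0, 0.5, 2), 2, 2,
#'                 dimnames = list(c("g1", "g2"), c("s1", "s2"))), 0.5)
#' @export
binarize <- function(m, threshold = 0.5) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    stop("threshold must be a single finite number")
  }
  if (!is.numeric(m)) {
    bad <- which(!vapply(as.vector(m), function(x) is.numeric(x) || is.na(x), TRUE))[1]
    rc <- arrayInd(bad, dim(m))
    stop("non-numeric cell at row ", rc[1], ", column ", rc[2])
  }
  if (anyNA(m)) {
    rc <- arrayInd(which(is.na(m))[1], dim(m))
    stop("missing value at row ", rc[1], ", column ", rc[2])
  }
  check_ids(m)
  out <- matrix(as.integer(m > threshold), nrow(m), ncol(m), dimnames = dimnames(m))
  out
}

check_ids <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must carry row and column identifiers as dimnames")
  }
  if (anyDuplicated(rownames(m))) stop("duplicated row ids")
  if (anyDuplicated(colnames(m))) stop("duplicated column ids")
  invisible(m)
}

new_example_set <- function(ids, labels) {
  stopifnot(nrow(ids) == length(labels), all(labels %in% c(0L, 1L)))
  ids$example <- seq_len(nrow(ids))
  ids$label <- as.integer(labels)
  structure(
    list(
      ids = tibble::as_tibble(ids[, c("example", "row_id", "col_id", "label")]),
      positives = ids$example[ids$label == 1L],
      negatives = ids$example[ids$label == 0L],
      n = nrow(ids)
    ),
    class = "example_set"
  )
}

#' Turn the cells of a binary matrix into labelled examples
#'
#' Every matrix cell is one example, identified by its (row id, column id)
#' pair; cells valued 1 form the positive class and cells valued 0 the
#' negative class. Examples are ordered row-major.
#'
#' @param m Binary (0/1) matrix with unique dimnames, e.g. from [binarize()].
#' @return An `example_set`: list with `ids` (tibble of `example`, `row_id`,
#'   `col_id`, `label`), `positives`, `negatives` (integer example indices)
#'   and `n`.
#' @export
cells_to_examples <- function(m) {
  check_ids(m)
  if (!all(m %in% c(0, 1))) stop("matrix is not binary; run binarize() first")
  ids <- data.frame(
    row_id = rep(rownames(m), each = ncol(m)),
    col_id = rep(colnames(m), times = nrow(m)),
    stringsAsFactors = FALSE
  )
  labels <- as.integer(t(m))
  new_example_set(ids, labels)
}

#' Build examples for a treatment-versus-control design
#'
#' For analyses restricted to significantly expressed genes, the example set
#' is formed from a pre-selected set of rows crossed with two disjoint column
#' groups: every (row, treatment column) cell is a positive example and every
#' (row, control column) cell a negative one. Matrix values are ignored in
#' this mode; only the identifiers matter.
#'
#' @param m Matrix supplying the universe of row/column ids.
#' @param sig_rows Row ids of the genes of interest.
#' @param treat_cols,ctrl_cols Disjoint sets of column ids.
#' @return An `example_set` with `length(sig_rows) * length(treat_cols)`
#'   positives and `length(sig_rows) * length(ctrl_cols)` negatives.
#' @export
treatment_control_examples <- function(m, sig_rows, treat_cols, ctrl_cols) {
  check_ids(m)
  sig_rows <- unique(as.character(sig_rows))
  treat_cols <- unique(as.character(treat_cols))
  ctrl_cols <- unique(as.character(ctrl_cols))
  unknown <- c(setdiff(sig_rows, rownames(m)),
               setdiff(c(treat_cols, ctrl_cols), colnames(m)))
  if (length(unknown)) stop("unknown row/column id(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(treat_cols, ctrl_cols))) {
    stop("treatment and control column groups overlap")
  }
  cols <- c(treat_cols, ctrl_cols)
  ids <- data.frame(
    row_id = rep(sig_rows, each = length(cols)),
    col_id = rep(cols, times = length(sig_rows)),
    stringsAsFactors = FALSE
  )
  labels <- as.integer(ids$col_id %in% treat_cols)
  new_example_set(ids, labels)
}

#' @export
print.example_set <- function(x, ...) {
  cat("<example_set: ", x$n, " examples (",
      length(x$positives), " positive, ", length(x$negatives),
      " negative)>\n", sep = "")
  invisible(x)
}

# Restrict an example set to a subset of example indices, keeping the
# original indices/ids so semantic covers stay valid across covering steps.
subset_examples <- function(e, keep) {
  structure(
    list(
      ids = e$ids,
      positives = intersect(e$positives, keep),
      negatives = intersect(e$negatives, keep),
      n = e$n
    ),
    class = "example_set"
  )
}

example_scope <- function(e) sort(c(e$positives, e$negatives))

#' Create or read an annotation map
#'
#' An annotation map links entities of one matrix axis (rows or columns) to
#' the ontology terms that directly annotate them. On file it is a
#' two-column, header-less TSV: entity id, term id, one pair per line.
#'
#' @param x Data frame whose first two columns are entity id and term id.
#' @param axis `"rows"` or `"columns"`: which matrix axis the entities
#'   belong to.
#' @return A tibble with columns `id`, `term` and attribute `axis`.
#' @export
annotation_map <- function(x, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  x <- as.data.frame(x)[, 1:2]
  names(x) <- c("id", "term")
  x$id <- as.character(x$id)
  x$term <- as.character(x$term)
  out <- tibble::as_tibble(unique(x))
  attr(out, "axis") <- axis
  class(out) <- c("annotation_map", class(out))
  out
}

#' @rdname annotation_map
#' @param file Path to a two-column TSV (entity id, term id).
#' @export
read_annotations <- function(file, axis = c("rows", "columns")) {
  df <- utils::read.table(file, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("id", "term"))
  annotation_map(df, axis)
}
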
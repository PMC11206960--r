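#' Coerce to a descriptor matrix
#'
#' A descriptor matrix is the package's working container for compounds x
#' molecular descriptors: a numeric `matrix` with unique row names (compound
#' ids) and unique column names (descriptor names). Missing descriptor values
#' are `NA`.
#'
#' @param x A numeric matrix or data frame. For a data frame, an `id` column
#'   (or the row names) supplies compound ids and all remaining columns must
#'   be numeric.
#' @return A validated numeric matrix with `dimnames`.
#' @export
as_descriptor_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("id" %in% names(x)) {
      ids <- as.character(x[["id"]])
      x <- x[, setdiff(names(x), "id"), drop = FALSE]
    } else {
      ids <- rownames(x)
    }
    x <- as.matrix(x)
    rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("descriptor matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("desc_%03d", seq_len(ncol(x)))
  }
  if (is.null(rownames(x))) {
    rownames(x) <- sprintf("cmp_%04d", seq_len(nrow(x)))
  }
  if (anyDuplicated(rownames(x))) stop("duplicate compound ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop("duplicate descriptor column(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  x
}

# Check that `m` carries every column in `cols`; error names the missing ones.
check_columns <- function(m, cols, context = "matrix") {
  miss <- setdiff(cols, colnames(m))
  if (length(miss)) {
    stop(context, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
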
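#' Construct a validated spectral-count matrix
#'
#' Bundles a protein-by-sample count matrix with its sample-to-group
#' assignment. Counts are non-negative integers on input and may become
#' non-integer after total-count normalization. Exactly two groups are
#' supported, labelled `"high"` and `"low"`; every downstream contrast is
#' high minus low.
#'
#' @param counts numeric matrix, proteins in rows (unique rownames), samples
#'   in columns (unique colnames); all values finite and >= 0.
#' @param groups named character vector mapping every sample id to `"high"`
#'   or `"low"`; both groups must contain at least 2 samples.
#' @param drop_all_zero drop proteins with zero counts in every sample
#'   (default `TRUE`); the number dropped is reported via `message()`.
#'
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts` (the matrix) and `groups` (the map, reordered to the column
#'   order of `counts`).
#' @export
count_matrix <- function(counts, groups, drop_all_zero = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have protein rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate protein ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)

  if (is.factor(groups)) groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups)))
    stop("`groups` must be a named vector (names are sample ids)", call. = FALSE)
  miss <- setdiff(colnames(counts), names(groups))
  if (length(miss))
    stop("samples missing from group map: ", paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(groups), colnames(counts))
  if (length(extra))
    stop("group map lists samples absent from the matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(groups)))
    stop("group map lists a sample more than once", call. = FALSE)
  groups <- groups[colnames(counts)]
  bad <- setdiff(unique(groups), c("high", "low"))
  if (length(bad))
    stop("group labels must be 'high' or 'low'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (sum(groups == "high") < 2 || sum(groups == "low") < 2)
    stop("each group needs at least 2 samples", call. = FALSE)

  if (drop_all_zero) {
    zero <- rowSums(counts) == 0
    if (any(zero)) {
      message(sum(zero), " protein(s) with zero counts in every sample dropped")
      counts <- counts[!zero, , drop = FALSE]
    }
    if (nrow(counts) == 0) stop("no proteins left after dropping all-zero rows", call. = FALSE)
  }

  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d proteins x %d samples (%d high, %d low)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "high"), sum(x$groups == "low")))
  cat("sample totals:", paste(format(round(colSums(x$counts), 2)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# sample indices per group, in matrix column order
group_index <- function(cm) {
  list(high = which(cm$groups == "high"), low = which(cm$groups == "low"))
}
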
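#' Row-standardize a matrix of log2 abundances
#'
#' Centers and scales each row to mean 0, sd 1 (the usual "normalize on
#' rows" step before two-way clustering, so every protein contributes its
#' expression pattern rather than its level). Constant rows have no
#' pattern and are dropped with a warning.
#'
#' @param x numeric matrix, proteins in rows, >= 2 columns.
#' @return The standardized matrix (possibly fewer rows).
#' @export
row_standardize <- function(x) {
  if (!is.matrix(x) || ncol(x) < 2) stop("need a matrix with >= 2 columns", call. = FALSE)
  sds <- apply(x, 1, sd)
  if (all(sds == 0)) stop("all rows are constant", call. = FALSE)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant row(s) dropped before standardization")
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (x - rowMeans(x)) / sds
}

#' Two-way agglomerative hierarchical clustering
#'
#' Clusters rows and columns of a (typically row-standardized) matrix with
#' Euclidean distance and average linkage by default. The two-cluster
#' column partition is read from the final merge of the column dendrogram;
#' when sample groups are supplied, purity is the proportion of samples
#' assigned consistently with their group under the better of the two
#' possible label mappings.
#'
#' @param x numeric matrix (>= 2 rows and columns, all finite).
#' @param groups optional named character vector of sample groups
#'   (names = column names of `x`).
#' @param distance [stats::dist()] method (default `"euclidean"`).
#' @param linkage [stats::hclust()] method (default `"average"`).
#' @return list of class `"cluster_result"`: `row_hclust`, `col_hclust`,
#'   `row_order`, `col_order` (leaf label permutations),
#'   `column_partition` (named 1/2 vector), `purity` (or `NA`).
#' @export
hierarchical_cluster <- function(x, groups = NULL, distance = "euclidean",
                                 linkage = "average") {
  if (!is.matrix(x) || nrow(x) < 2 || ncol(x) < 2)
    stop("need a matrix with >= 2 rows and >= 2 columns", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite entries in clustering input", call. = FALSE)
  rh <- hclust(dist(x, method = distance), method = linkage)
  ch <- hclust(dist(t(x), method = distance), method = linkage)
  part <- cutree(ch, k = 2)
  purity <- NA_real_
  if (!is.null(groups)) {
    g <- groups[colnames(x)]
    agree <- mean((part == 1) == (g == "high"))
    purity <- max(agree, 1 - agree)
  }
  structure(list(row_hclust = rh, col_hclust = ch,
                 row_order = rownames(x)[rh$order],
                 col_order = colnames(x)[ch$order],
                 column_partition = part, purity = purity),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d rows x %d columns", length(x$row_order),
              length(x$col_order)))
  if (!is.na(x$purity)) cat(sprintf(", two-cluster column purity %.2f", x$purity))
  cat("\ncolumn order:", paste(x$col_order, collapse = " "), "\n")
  invisible(x)
}

#' Export a clustered heat-map matrix
#'
#' Writes the matrix reordered to the dendrogram leaf orders as TSV
#' (always) and optionally renders a PNG with a green-black-red diverging
#' palette.
#'
#' @param cr a `"cluster_result"`.
#' @param x the matrix that was clustered.
#' @param tsv_path output TSV path.
#' @param png_path optional PNG path (default `NULL`, no image).
#' @return Invisibly, the reordered matrix.
#' @export
export_heatmap <- function(cr, x, tsv_path, png_path = NULL) {
  ord <- x[cr$row_order, cr$col_order, drop = FALSE]
  write_tsv_matrix(ord, tsv_path, id_col = "protein")
  if (!is.null(png_path)) {
    pal <- colorRampPalette(c("green", "black", "red"))(64)
    png(png_path, width = 640, height = 960)
    image(t(ord[rev(seq_len(nrow(ord))), , drop = FALSE]), col = pal,
          axes = FALSE)
    dev.off()
  }
  invisible(ord)
}
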
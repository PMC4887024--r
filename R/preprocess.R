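#' Total-spectral-count normalization
#'
#' Equalizes library size across samples: every sample's counts are scaled
#' by (grand mean of sample totals) / (that sample's total), so that all
#' post-normalization sample totals equal the grand mean. The operation is
#' idempotent and absorbs any common rescaling of the raw counts, which is
#' why downstream M values do not depend on sequencing (spectral) depth.
#'
#' @param m a [count_matrix()].
#' @return The normalized `count_matrix` (counts now non-integer reals).
#' @export
normalize_total_counts <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- colSums(m$counts)
  if (any(totals == 0))
    stop("sample(s) with zero total counts: ",
         paste(names(totals)[totals == 0], collapse = ", "), call. = FALSE)
  scale <- mean(totals) / totals
  m$counts <- sweep(m$counts, 2, scale, "*")
  m
}

#' Build the MA table of log2 group means
#'
#' Per-sample abundances are log2-transformed after adding a small
#' pseudo-count (to handle zeros), then averaged within each group.
#' M is the high-minus-low difference of group means; A_raw is their
#' average; A is the "justified" abundance `A_raw + a_offset`, shifted so
#' that essentially all observed proteins carry a positive abundance
#' weight in the PIF step. A can still be negative for proteins whose
#' abundance is below the pseudo-count scale (an all-zero protein has
#' `A = log2(pseudo_count) + a_offset`).
#'
#' @param m a normalized [count_matrix()] (see [normalize_total_counts()]).
#' @param pseudo_count added to every value before log2 (default 0.05);
#'   must be > 0 if any count is zero.
#' @param a_offset added to A_raw to justify abundances (default 4).
#' @return data.frame of class `"ma_table"` with columns `protein`,
#'   `mean_high`, `mean_low`, `M`, `A_raw`, `A`.
#' @export
compute_ma <- function(m, pseudo_count = 0.05, a_offset = 4) {
  stopifnot(inherits(m, "count_matrix"))
  if (pseudo_count < 0) stop("pseudo_count must be >= 0", call. = FALSE)
  if (pseudo_count == 0 && any(m$counts == 0))
    stop("pseudo_count = 0 with zero counts would give -Inf log abundances",
         call. = FALSE)
  idx <- group_index(m)
  L <- log2(m$counts + pseudo_count)
  mean_high <- rowMeans(L[, idx$high, drop = FALSE])
  mean_low <- rowMeans(L[, idx$low, drop = FALSE])
  M <- mean_high - mean_low
  A_raw <- (mean_high + mean_low) / 2
  structure(data.frame(protein = rownames(m$counts),
                       mean_high = mean_high, mean_low = mean_low,
                       M = M, A_raw = A_raw, A = A_raw + a_offset,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("ma_table", "data.frame"),
            pseudo_count = pseudo_count, a_offset = a_offset)
}
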
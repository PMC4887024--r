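#' Overlay a compartment annotation on an MA table
#'
#' Matches a symbol list (e.g. a mitoproteome download) against the
#' proteins of an MA table. Matching is case-insensitive exact string
#' comparison after whitespace trimming; duplicate list entries count
#' once.
#'
#' @param ma an `"ma_table"` (or any data.frame with a `protein` column).
#' @param symbols character vector of annotation symbols.
#' @return The matched rows, with `attr(, "n_listed")` and
#'   `attr(, "n_matched")`. Zero matches give an empty data.frame with a
#'   warning, not an error.
#' @export
overlay_annotation <- function(ma, symbols) {
  if (length(symbols) == 0) stop("empty symbol list", call. = FALSE)
  symbols <- unique(toupper(trimws(symbols)))
  hit <- toupper(trimws(ma$protein)) %in% symbols
  if (!any(hit)) warning("no annotation symbols matched the dataset")
  structure(ma[hit, , drop = FALSE],
            n_listed = length(symbols), n_matched = sum(hit))
}

#' Exact binomial test for directional skew
#'
#' Tests whether the signs of a set of M values deviate from the 50:50
#' equilibrium expected when a compartment's proteins are exchangeable
#' between groups. Ties (M exactly 0) carry no direction and are excluded
#' from n. The default two-sided p doubles the smaller exact tail and caps
#' at 1; `method = "minlik"` instead sums all outcomes no more likely than
#' the observed one (the [stats::binom.test()] convention).
#'
#' @param M numeric vector of matched log2 group differences (high - low).
#' @param method `"doubling"` (default) or `"minlik"`.
#' @return list of class `"skew_report"`: `k_pos`, `k_neg`, `n_ties`, `n`,
#'   `p_binom`, `method`.
#' @export
binomial_skew_test <- function(M, method = c("doubling", "minlik")) {
  method <- match.arg(method)
  k_pos <- sum(M > 0)
  k_neg <- sum(M < 0)
  n_ties <- sum(M == 0)
  n <- k_pos + k_neg
  if (n < 1) stop("no informative signs (all M values are ties)", call. = FALSE)
  p <- if (method == "doubling") {
    lower <- pbinom(k_pos, n, 0.5)
    upper <- pbinom(k_pos - 1, n, 0.5, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  } else {
    binom.test(k_pos, n, 0.5)$p.value
  }
  structure(list(k_pos = k_pos, k_neg = k_neg, n_ties = n_ties, n = n,
                 p_binom = p, method = method), class = "skew_report")
}

#' @export
print.skew_report <- function(x, ...) {
  cat(sprintf("binomial skew: %d positive / %d negative (%d ties excluded), two-sided p = %.4g [%s]\n",
              x$k_pos, x$k_neg, x$n_ties, x$p_binom, x$method))
  invisible(x)
}

#' Compartment-proteome skew report
#'
#' Full compartment analysis: overlay the symbol list on the MA table,
#' test the matched proteins' M signs for deviation from 50:50, and count
#' how many matched proteins fall in each extreme PIF tail.
#'
#' @inheritParams overlay_annotation
#' @inheritParams binomial_skew_test
#' @param tails optional tail sets from [select_extreme()] for the
#'   tail-overlap counts.
#' @return list of class `"skew_report"` extended with `n_listed`,
#'   `n_matched`, `tail_overlap_up`, `tail_overlap_down`.
#' @export
mito_skew_report <- function(ma, symbols, tails = NULL,
                             method = c("doubling", "minlik")) {
  matched <- overlay_annotation(ma, symbols)
  if (nrow(matched) == 0) {
    rep <- structure(list(k_pos = 0L, k_neg = 0L, n_ties = 0L, n = 0L,
                          p_binom = NA_real_, method = match.arg(method)),
                     class = "skew_report")
  } else {
    rep <- binomial_skew_test(matched$M, method)
  }
  rep$n_listed <- attr(matched, "n_listed")
  rep$n_matched <- attr(matched, "n_matched")
  if (!is.null(tails)) {
    rep$tail_overlap_up <- length(intersect(matched$protein, tails$up))
    rep$tail_overlap_down <- length(intersect(matched$protein, tails$down))
  }
  rep
}
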
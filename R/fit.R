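#' Fit the spectral-count PIF analysis
#'
#' The central fitting function: normalizes a raw count matrix to equal
#' sample totals, builds the log2 MA representation, estimates the
#' empirical-Bayes variance prior, computes moderated t-statistics and the
#' fold-change/significance DE filter, and ranks proteins by the
#' Phenotypic Impact Factor with extreme-tail and top-k selection.
#'
#' @param counts a [count_matrix()], or a raw numeric matrix (then
#'   `groups` is required).
#' @param groups named character vector of sample groups when `counts` is
#'   a bare matrix.
#' @param pseudo_count added before log2 and in fold-change denominators
#'   (default 0.05).
#' @param a_offset abundance justification offset (default 4).
#' @param tail_fraction per-tail PIF fraction in (0, 0.5) (default 0.05).
#' @param top_k even number of top PIF proteins (default 40).
#' @param min_fold,max_fold,alpha DE filter (defaults 1.3, 15, 0.05).
#' @param use_justified_pif weight PIF by the justified A (default) or
#'   raw A.
#'
#' @return An object of class `"pif_fit"`: a list with `normalized`
#'   (count_matrix), `ma` (ma_table), `de` (de_result), `pif` (annotated
#'   pif_table with `tail` and `topk_rank`), `tails`, `topk`, `prior`
#'   (`d0`, `s0_2`) and `params`. Methods: `print`, `summary`, `coef`,
#'   `plot`.
#' @examples
#' sim <- simulate_counts(sim_config(n_proteins = 300, seed = 42))
#' fit <- pif_fit(sim$counts)
#' summary(fit)
#' @export
pif_fit <- function(counts, groups = NULL, pseudo_count = 0.05, a_offset = 4,
                    tail_fraction = 0.05, top_k = 40, min_fold = 1.3,
                    max_fold = 15, alpha = 0.05, use_justified_pif = TRUE) {
  if (!inherits(counts, "count_matrix")) counts <- count_matrix(counts, groups)
  else if (any(rowSums(counts$counts) == 0))
    counts <- count_matrix(counts$counts, counts$groups)  # apply all-zero drop
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop("tail_fraction must be in (0, 0.5)", call. = FALSE)
  if (min_fold <= 1 || min_fold > max_fold)
    stop("need 1 < min_fold <= max_fold", call. = FALSE)

  nm <- normalize_total_counts(counts)
  ma <- compute_ma(nm, pseudo_count, a_offset)
  de <- de_table(nm, pseudo_count, min_fold, max_fold, alpha)
  pif <- compute_pif(ma, use_justified = use_justified_pif)
  tails <- select_extreme(pif, tail_fraction)
  topk <- top_k_by_pif(pif, top_k)
  pif <- annotate_pif(pif, tails, topk)

  structure(list(normalized = nm, ma = ma, de = de, pif = pif,
                 tails = tails, topk = topk, prior = attr(de, "prior"),
                 params = list(pseudo_count = pseudo_count, a_offset = a_offset,
                               tail_fraction = tail_fraction, top_k = top_k,
                               min_fold = min_fold, max_fold = max_fold,
                               alpha = alpha,
                               use_justified_pif = use_justified_pif)),
            class = "pif_fit")
}

#' @export
print.pif_fit <- function(x, ...) {
  filt <- de_filter(x$de, x$params$min_fold, x$params$max_fold, x$params$alpha)
  cat(sprintf("pif_fit: %d proteins, %d + %d samples (high/low)\n",
              nrow(x$normalized$counts),
              sum(x$normalized$groups == "high"),
              sum(x$normalized$groups == "low")))
  cat(sprintf("  DE (|fold| in [%.2g, %.2g], p < %.2g): %d up, %d down\n",
              x$params$min_fold, x$params$max_fold, x$params$alpha,
              attr(filt, "n_up"), attr(filt, "n_down")))
  cat(sprintf("  PIF tails: %d per tail (%.0f%%); top-%d ranked\n",
              x$tails$k, 100 * x$params$tail_fraction, x$params$top_k))
  invisible(x)
}

#' @export
summary.pif_fit <- function(object, ...) {
  filt <- de_filter(object$de, object$params$min_fold, object$params$max_fold,
                    object$params$alpha)
  out <- list(n_proteins = nrow(object$normalized$counts),
              n_high = sum(object$normalized$groups == "high"),
              n_low = sum(object$normalized$groups == "low"),
              d0 = object$prior$d0, s0_2 = object$prior$s0_2,
              n_de = nrow(filt), n_up = attr(filt, "n_up"),
              n_down = attr(filt, "n_down"), tail_size = object$tails$k,
              top_k = object$params$top_k, params = object$params)
  class(out) <- "summary.pif_fit"
  out
}

#' @export
print.summary.pif_fit <- function(x, ...) {
  cat(sprintf("Proteins quantified:        %d\n", x$n_proteins))
  cat(sprintf("Samples:                    %d high, %d low\n", x$n_high, x$n_low))
  cat(sprintf("Variance prior:             d0 = %s, s0^2 = %.4g\n",
              if (is.infinite(x$d0)) "Inf" else sprintf("%.3f", x$d0), x$s0_2))
  cat(sprintf("DE proteins (filter):       %d (%d up, %d down)\n",
              x$n_de, x$n_up, x$n_down))
  cat(sprintf("Extreme PIF tails:          %d up + %d down = %d\n",
              x$tail_size, x$tail_size, 2 * x$tail_size))
  cat(sprintf("Top PIF proteins clustered: %d\n", x$top_k))
  invisible(x)
}

#' Extract per-protein coefficients from a fit
#'
#' @param object a `"pif_fit"`.
#' @param type `"fold"` (signed fold change, default), `"M"` (log2
#'   difference) or `"pif"`.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.pif_fit <- function(object, type = c("fold", "M", "pif"), ...) {
  type <- match.arg(type)
  v <- switch(type, fold = object$de$fold, M = object$de$M,
              pif = object$pif$pif)
  stats::setNames(v, object$de$protein)
}

#' MA plot of a fitted analysis
#'
#' Scatter of M against justified A with the extreme PIF tails
#' highlighted in blue and, optionally, a compartment annotation overlaid
#' in red.
#'
#' @param x a `"pif_fit"`.
#' @param compartment optional character vector of symbols to overlay.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.pif_fit <- function(x, compartment = NULL, ...) {
  in_tail <- x$pif$tail != "none"
  plot(x$ma$A, x$ma$M, pch = 20, cex = 0.5, col = "grey50",
       xlab = "A (justified mean log2 abundance)",
       ylab = "M (log2 high - low)", ...)
  abline(h = 0, lty = 2)
  points(x$ma$A[in_tail], x$ma$M[in_tail], pch = 20, cex = 0.6, col = "blue")
  if (!is.null(compartment)) {
    hit <- toupper(trimws(x$ma$protein)) %in% unique(toupper(trimws(compartment)))
    points(x$ma$A[hit], x$ma$M[hit], pch = 1, cex = 0.8, col = "red")
    legend("topleft", legend = c("PIF tail", "compartment"),
           col = c("blue", "red"), pch = c(20, 1), bty = "n")
  } else {
    legend("topleft", legend = "PIF tail", col = "blue", pch = 20, bty = "n")
  }
  invisible(x)
}

#' Group contrast of a per-sample phenotype
#'
#' Difference of group means (high minus low) of any per-sample
#' measurement, e.g. the feed-efficiency values of the phenotyping trial.
#'
#' @param values named numeric vector (names = sample ids).
#' @param groups named character vector of groups for those samples.
#' @return numeric: `mean(high) - mean(low)`.
#' @export
group_contrast <- function(values, groups) {
  if (is.null(names(values)) || is.null(names(groups)))
    stop("values and groups must be named by sample id", call. = FALSE)
  g <- groups[names(values)]
  if (any(is.na(g))) stop("samples missing from the group map", call. = FALSE)
  mean(values[g == "high"]) - mean(values[g == "low"])
}
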
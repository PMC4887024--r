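#' Phenotypic Impact Factor
#'
#' PIF weights each protein's differential expression by its abundance:
#' `pif = A * M`, with A the justified average abundance and M the log2
#' group difference. The weighting de-emphasizes lowly abundant proteins,
#' which sit near the detection limit of spectral counting and are
#' inherently noisier, so extreme PIF values track the edges of the MA
#' distribution.
#'
#' @param ma an `"ma_table"` from [compute_ma()].
#' @param use_justified use the justified abundance `A` (default) or the
#'   raw `A_raw` as the weight.
#' @return data.frame of class `"pif_table"` with `protein`, `A`, `M`,
#'   `pif`.
#' @export
compute_pif <- function(ma, use_justified = TRUE) {
  a <- if (use_justified) ma$A else ma$A_raw
  structure(data.frame(protein = ma$protein, A = a, M = ma$M, pif = a * ma$M,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("pif_table", "data.frame"))
}

# deterministic extreme-tail ordering: pif, then |M|, then protein id
order_tail <- function(pif, up = TRUE) {
  if (up) order(-pif$pif, -abs(pif$M), pif$protein)
  else    order(pif$pif, -abs(pif$M), pif$protein)
}

#' Select the extreme PIF tails
#'
#' Takes the `tail_fraction` most up- and most down-regulated proteins by
#' PIF. The per-tail size is `round(tail_fraction * N)` with halves rounded
#' away from zero (0.05 x 1817 = 90.85 -> 91). Boundary ties are broken by
#' larger |M|, then lexicographic protein id, so the selection is
#' deterministic.
#'
#' @param pif a `"pif_table"` from [compute_pif()].
#' @param tail_fraction per-tail proportion in (0, 0.5) (default 0.05).
#' @return list with character vectors `up` and `down` (each of length
#'   `k = round(tail_fraction * N)`) and the per-tail size `k`.
#' @export
select_extreme <- function(pif, tail_fraction = 0.05) {
  n <- nrow(pif)
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop("tail_fraction must be in (0, 0.5): tails would overlap", call. = FALSE)
  k <- floor(tail_fraction * n + 0.5)  # round half away from zero
  if (k < 1) stop("tail_fraction too small: empty tails", call. = FALSE)
  up <- pif$protein[order_tail(pif, up = TRUE)][seq_len(k)]
  down <- pif$protein[order_tail(pif, up = FALSE)][seq_len(k)]
  if (length(intersect(up, down)))
    stop("tails overlap; reduce tail_fraction", call. = FALSE)
  list(up = up, down = down, k = k)
}

#' Top-k proteins by PIF
#'
#' The `k/2` largest and `k/2` smallest PIF proteins with their ranks
#' (rank 1 = most extreme within each direction), using the same
#' deterministic tie-breaking as [select_extreme()].
#'
#' @param pif a `"pif_table"`.
#' @param k even number of proteins to keep (default 40).
#' @return data.frame with `protein`, `pif`, `direction` ("up"/"down"),
#'   `rank`.
#' @export
top_k_by_pif <- function(pif, k = 40) {
  if (k %% 2 != 0) stop("k must be even (k/2 up and k/2 down)", call. = FALSE)
  if (k > nrow(pif)) stop("k exceeds the number of proteins", call. = FALSE)
  half <- k / 2
  up <- order_tail(pif, up = TRUE)[seq_len(half)]
  down <- order_tail(pif, up = FALSE)[seq_len(half)]
  data.frame(protein = c(pif$protein[up], pif$protein[down]),
             pif = c(pif$pif[up], pif$pif[down]),
             direction = rep(c("up", "down"), each = half),
             rank = c(seq_len(half), seq_len(half)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# assemble the full per-protein PIF table with tail and top-k annotations
annotate_pif <- function(pif, tails, topk) {
  pif$tail <- "none"
  pif$tail[pif$protein %in% tails$up] <- "up"
  pif$tail[pif$protein %in% tails$down] <- "down"
  pif$topk_rank <- NA_integer_
  pif$topk_rank[match(topk$protein, pif$protein)] <- topk$rank
  pif
}
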
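#' Two-list hypergeometric enrichment
#'
#' For each term, tests whether the target list contains more term members
#' than expected from random draws out of the background:
#' `p = P[X >= k]` with `X ~ Hypergeometric(N, K, n)` where N is the
#' background size, K the term members present in the background, n the
#' target-list size and k the term members in the target list. Terms with
#' no member in the background are skipped; Benjamini-Hochberg q-values
#' are computed over the tested terms.
#'
#' @param target character vector, the protein list of interest (must be a
#'   subset of `background`).
#' @param background character vector, the universe of observed proteins.
#' @param terms named list of character vectors (term -> member symbols),
#'   e.g. from [read_gmt()].
#' @return data.frame of class `"enrichment_result"` with `term`, `K`,
#'   `k`, `N`, `n`, `p_hyper`, `q`, ordered by increasing p.
#' @export
hypergeom_enrichment <- function(target, background, terms) {
  target <- unique(target); background <- unique(background)
  if (length(background) < 2) stop("background must contain >= 2 proteins", call. = FALSE)
  out <- setdiff(target, background)
  if (length(out))
    stop("target proteins absent from the background: ",
         paste(out, collapse = ", "), call. = FALSE)
  N <- length(background); n <- length(target)
  rows <- lapply(names(terms), function(tm) {
    members <- intersect(unique(terms[[tm]]), background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, target))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, K = K, k = k, N = N, n = n, p_hyper = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    res <- data.frame(term = character(), K = integer(), k = integer(),
                      N = integer(), n = integer(), p_hyper = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
    return(structure(res, class = c("enrichment_result", "data.frame")))
  }
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p_hyper)
  res <- res[order(res$p_hyper, res$term), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR q-values: `q_(i) = min_{j >= i} p_(j) * m / j` over the
#' sorted p-values, with ties handled stably.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Upstream-regulator activation z-scores
#'
#' For each regulator, compares the observed expression direction of its
#' known targets with the literature-expected regulation direction. A
#' target is informative when it has an observed DE sign and a known
#' expected direction; its consistency with regulator activation is
#' `expected direction * observed sign`. The activation z-score is
#' `(n_consistent_activation - n_consistent_inhibition) / sqrt(N)`, so
#' `|z| = sqrt(N)` exactly when every informative target agrees, positive
#' z supporting activation and negative z inhibition.
#'
#' @param network data.frame with columns `regulator`, `target`,
#'   `direction` (+1 the regulator activates the target, -1 represses).
#' @param observed named numeric vector of observed DE signs (+1/-1) for
#'   the proteins in the DE set; targets absent from it are
#'   non-informative.
#' @return data.frame with one row per regulator: `regulator`,
#'   `n_informative`, `n_consistent_activation`,
#'   `n_consistent_inhibition`, `z` (`NA` when no informative target).
#' @export
activation_z <- function(network, observed) {
  stopifnot(all(c("regulator", "target", "direction") %in% names(network)))
  if (length(observed) && is.null(names(observed)))
    stop("`observed` must be a named vector of DE signs", call. = FALSE)
  regs <- unique(network$regulator)
  rows <- lapply(regs, function(r) {
    ed <- network[network$regulator == r, , drop = FALSE]
    obs <- observed[match(ed$target, names(observed))]
    info <- !is.na(obs) & sign(obs) != 0
    consist <- ed$direction[info] * sign(obs[info])
    n_act <- sum(consist > 0); n_inh <- sum(consist < 0)
    n <- n_act + n_inh
    data.frame(regulator = r, n_informative = n,
               n_consistent_activation = n_act,
               n_consistent_inhibition = n_inh,
               z = if (n > 0) (n_act - n_inh) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sided Fisher overlap p-value
#'
#' Probability of observing at least the seen overlap between a
#' regulator's target set and the DE set when drawing from the background,
#' i.e. the upper hypergeometric tail of the 2x2 table (equivalently a
#' one-sided Fisher exact test in the enrichment direction).
#'
#' @param targets character vector of the regulator's targets (within the
#'   background).
#' @param de_set character vector of DE proteins (within the background).
#' @param background character vector, the observed universe.
#' @return numeric p-value.
#' @export
overlap_p <- function(targets, de_set, background) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  targets <- intersect(unique(targets), background)
  de_set <- intersect(unique(de_set), background)
  k <- length(intersect(targets, de_set))
  phyper(k - 1, length(targets), length(background) - length(targets),
         length(de_set), lower.tail = FALSE)
}

#' Classify a regulator's predicted activity
#'
#' Applies the activation bands: a call requires `p_overlap < alpha`;
#' `|z| > z_threshold` gives "activated"/"inhibited" by sign, and smaller
#' |z| gives qualified calls — strong (`|z| >= 1.7`), moderate
#' (`1.5 <= |z| < 1.7`), weak (`1.0 < |z| < 1.5`) — with the sign carried
#' as a suffix. `|z|` exactly at the threshold falls in the qualified
#' strong band (activation requires strictly greater). Everything else is
#' "none".
#'
#' @param z numeric vector of activation z-scores (`NA` allowed: "none").
#' @param p_overlap numeric vector of overlap p-values.
#' @param z_threshold activation threshold (default 2.0).
#' @param bands decreasing cut points for strong/moderate/weak qualified
#'   calls (default `c(1.7, 1.5, 1.0)`).
#' @param alpha overlap significance requirement (default 0.05).
#' @return character vector of states: "activated", "inhibited",
#'   "strong+", "strong-", "moderate+", "moderate-", "weak+", "weak-",
#'   "none".
#' @export
classify_regulator <- function(z, p_overlap, z_threshold = 2,
                               bands = c(1.7, 1.5, 1.0), alpha = 0.05) {
  if (length(bands) != 3 || any(diff(bands) >= 0) || any(bands <= 0))
    stop("bands must be three strictly decreasing positive cut points", call. = FALSE)
  mapply(function(zi, pi) {
    if (is.na(zi) || is.na(pi) || pi >= alpha) return("none")
    a <- abs(zi); sfx <- if (zi > 0) "+" else "-"
    if (a > z_threshold) return(if (zi > 0) "activated" else "inhibited")
    if (a >= bands[1]) return(paste0("strong", sfx))
    if (a >= bands[2]) return(paste0("moderate", sfx))
    if (a > bands[3]) return(paste0("weak", sfx))
    "none"
  }, z, p_overlap, USE.NAMES = FALSE)
}

#' Full upstream-regulator prediction table
#'
#' Combines [activation_z()], [overlap_p()] and [classify_regulator()]
#' for a DE result: observed signs are the fold-change signs of the
#' proteins passing the DE filter, and the background is the full set of
#' quantified proteins.
#'
#' @param network regulator-target network (see [activation_z()]).
#' @param de a `"de_result"` from [de_table()].
#' @inheritParams classify_regulator
#' @return data.frame of class `"regulator_prediction"` with the
#'   activation counts, `z`, `p_overlap` and `state` per regulator.
#' @export
regulator_predictions <- function(network, de, z_threshold = 2,
                                  bands = c(1.7, 1.5, 1.0), alpha = 0.05) {
  de_rows <- de[de$pass_de, , drop = FALSE]
  observed <- stats::setNames(sign(de_rows$fold), de_rows$protein)
  res <- activation_z(network, observed)
  res$p_overlap <- vapply(res$regulator, function(r) {
    overlap_p(network$target[network$regulator == r], de_rows$protein,
              de$protein)
  }, numeric(1))
  res$state <- classify_regulator(res$z, res$p_overlap, z_threshold, bands, alpha)
  structure(res, class = c("regulator_prediction", "data.frame"))
}
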
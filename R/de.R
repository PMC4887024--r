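#' Signed fold change on the normalized count scale
#'
#' Ratio of group mean normalized counts, pseudo-count guarded, folded to
#' the signed convention with magnitude >= 1: positive folds mark proteins
#' up-regulated in the high group, negative folds proteins up-regulated in
#' the low group, and equal means give exactly +1. The pseudo-count keeps
#' folds finite when a protein is absent from one group.
#'
#' @param m a normalized [count_matrix()].
#' @param pseudo_count added to both group means before the ratio
#'   (default 0.05).
#' @return named numeric vector of signed folds.
#' @export
signed_fold_change <- function(m, pseudo_count = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  idx <- group_index(m)
  mh <- rowMeans(m$counts[, idx$high, drop = FALSE])
  ml <- rowMeans(m$counts[, idx$low, drop = FALSE])
  r <- (mh + pseudo_count) / (ml + pseudo_count)
  ifelse(r >= 1, r, -1 / r)
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior `sigma_g^2 ~ s0^2 * d0 / X_d0`
#' for per-protein variances by moments on the log scale. With
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
#' freedom solve `trigamma(d0/2) = var(e) - trigamma(d_g/2)` (monotone
#' root-finding); when the right-hand side is non-positive the variances
#' are less dispersed than sampling alone predicts and `d0 = Inf`. The
#' prior variance is `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`; at
#' the `d0 = Inf` boundary it is the plain mean of the variances.
#'
#' Non-positive variances carry no information on the log scale and are
#' excluded from the fit (with a warning when present).
#'
#' @param s2 numeric vector of per-protein pooled variances (>= 10 finite
#'   positive values required).
#' @param d_g residual degrees of freedom of each `s2` (scalar,
#'   `n_high + n_low - 2`).
#' @return list with `d0` (possibly `Inf`) and `s0_2`.
#' @export
fit_variance_prior <- function(s2, d_g) {
  if (d_g < 1) stop("d_g must be >= 1", call. = FALSE)
  if (all(s2 == 0, na.rm = TRUE)) stop("all variances are zero", call. = FALSE)
  ok <- is.finite(s2) & s2 > 0
  if (any(!ok)) warning(sum(!ok), " non-positive or non-finite variance(s) excluded from prior fit")
  s2 <- s2[ok]
  if (length(s2) < 10)
    stop("need at least 10 positive finite variances to fit the prior", call. = FALSE)
  e <- log(s2) - digamma(d_g / 2) + log(d_g / 2)
  rhs <- var(e) - trigamma(d_g / 2)
  if (rhs <= 0) {
    # variances less dispersed than sampling noise alone: infinite prior df.
    # At this boundary the common variance is estimated by the plain mean
    # (the log-scale bias correction no longer applies).
    return(list(d0 = Inf, s0_2 = mean(s2)))
  }
  f <- function(x) trigamma(x / 2) - rhs
  # trigamma(x/2) decreases from +Inf to 0: bracket then root-find
  d0 <- uniroot(f, lower = 1e-6, upper = 1e8, tol = 1e-10)$root
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated t-statistics with an empirical-Bayes variance prior
#'
#' Shrinks each per-protein variance towards the prior,
#' `s2_tilde = (d0*s0_2 + d_g*s2) / (d0 + d_g)` (limit `s0_2` as
#' `d0 -> Inf`), and tests `M` against a Student-t reference with
#' `d0 + d_g` degrees of freedom (normal tail when infinite). At `d0 = 0`
#' this is the ordinary pooled two-sample t-test.
#'
#' @param M numeric vector of log2 group-mean differences (high - low).
#' @param s2 per-protein pooled variances of the log2 abundances.
#' @param d0,s0_2 prior hyperparameters from [fit_variance_prior()].
#' @param n_high,n_low group sizes (each >= 2).
#' @return data.frame with `s2_tilde`, `t_mod`, `df_total`, `p`
#'   (two-sided). A zero moderated variance with nonzero M yields the
#'   sentinel `p = 0` with a warning.
#' @export
moderated_t <- function(M, s2, d0, s0_2, n_high, n_low) {
  if (n_high < 2 || n_low < 2) stop("group sizes must be >= 2", call. = FALSE)
  d_g <- n_high + n_low - 2
  s2_tilde <- if (is.infinite(d0)) rep(s0_2, length(s2))
              else (d0 * s0_2 + d_g * s2) / (d0 + d_g)
  se <- sqrt(s2_tilde * (1 / n_high + 1 / n_low))
  t_mod <- ifelse(M == 0, 0, M / se)
  df_total <- d0 + d_g
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  degenerate <- s2_tilde == 0 & M != 0
  if (any(degenerate)) {
    warning(sum(degenerate), " protein(s) with zero moderated variance and nonzero M; p set to 0")
    t_mod[degenerate] <- sign(M[degenerate]) * Inf
    p[degenerate] <- 0
  }
  data.frame(s2_tilde = s2_tilde, t_mod = t_mod, df_total = df_total, p = p)
}

# per-protein pooled variance of log2 abundances, df = n_high + n_low - 2
pooled_log2_variance <- function(m, pseudo_count = 0.05) {
  idx <- group_index(m)
  L <- log2(m$counts + pseudo_count)
  vh <- apply(L[, idx$high, drop = FALSE], 1, var)
  vl <- apply(L[, idx$low, drop = FALSE], 1, var)
  nh <- length(idx$high); nl <- length(idx$low)
  ((nh - 1) * vh + (nl - 1) * vl) / (nh + nl - 2)
}

#' Full differential-expression table for a normalized count matrix
#'
#' Convenience wrapper chaining [compute_ma()], [signed_fold_change()],
#' [fit_variance_prior()] and [moderated_t()], then applying the DE filter.
#'
#' @inheritParams compute_ma
#' @inheritParams de_filter
#' @return data.frame of class `"de_result"` with per-protein `fold`,
#'   `M`, `s2`, `s2_tilde`, `t_mod`, `df_total`, `p`, `t_ordinary`
#'   (no-shrinkage diagnostic) and `pass_de`; hyperparameters in
#'   `attr(, "prior")`.
#' @export
de_table <- function(m, pseudo_count = 0.05, min_fold = 1.3, max_fold = 15,
                     alpha = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  idx <- group_index(m)
  nh <- length(idx$high); nl <- length(idx$low)
  ma <- compute_ma(m, pseudo_count = pseudo_count)
  s2 <- pooled_log2_variance(m, pseudo_count)
  prior <- fit_variance_prior(s2, nh + nl - 2)
  mt <- moderated_t(ma$M, s2, prior$d0, prior$s0_2, nh, nl)
  se_ord <- sqrt(s2 * (1 / nh + 1 / nl))
  t_ord <- ifelse(ma$M == 0, 0, ma$M / se_ord)
  out <- data.frame(protein = ma$protein, fold = signed_fold_change(m, pseudo_count),
                    M = ma$M, s2 = s2, s2_tilde = mt$s2_tilde,
                    t_mod = mt$t_mod, df_total = mt$df_total, p = mt$p,
                    t_ordinary = t_ord, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$pass_de <- abs(out$fold) >= min_fold & abs(out$fold) <= max_fold &
    out$p < alpha
  structure(out, class = c("de_result", "data.frame"), prior = prior,
            filter = list(min_fold = min_fold, max_fold = max_fold, alpha = alpha))
}

#' Filter a DE table on fold-change band and significance
#'
#' Keeps proteins changed by at least `min_fold` and at most `max_fold`
#' (both boundaries inclusive, on the fold magnitude) with `p < alpha`.
#'
#' @param de a `"de_result"` data.frame (or any data.frame with `fold` and
#'   `p` columns).
#' @param min_fold,max_fold fold-magnitude band (defaults 1.3 and 15).
#' @param alpha significance threshold on the raw p-value (default 0.05;
#'   no multiplicity correction is applied at this stage).
#' @return The filtered rows, with the up/down split in
#'   `attr(, "n_up")` / `attr(, "n_down")`.
#' @export
de_filter <- function(de, min_fold = 1.3, max_fold = 15, alpha = 0.05) {
  if (min_fold > max_fold) stop("min_fold must be <= max_fold", call. = FALSE)
  keep <- abs(de$fold) >= min_fold & abs(de$fold) <= max_fold & de$p < alpha
  out <- de[keep, , drop = FALSE]
  structure(out, n_up = sum(out$fold > 0), n_down = sum(out$fold < 0))
}
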
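#' Configuration for the synthetic spectral-count generator
#'
#' Defines the study conditions emulated by [simulate_counts()]: a
#' two-group (high/low) design with `n_per_group` samples per group,
#' `n_proteins` proteins whose baseline abundances follow a heavy-tailed
#' lognormal, negative-binomial counts with variance `mu + dispersion*mu^2`,
#' a planted fraction of differentially expressed proteins, and a
#' compartment subset (e.g. the mitoproteome) whose planted effects are
#' biased towards the high group.
#'
#' Defaults mirror a typical broiler breast-muscle shotgun-proteomics
#' dataset: 1817 proteins, 4 birds per feed-efficiency group, a 228-protein
#' mitochondrial compartment with a 3:1 up bias, and roughly 8% of proteins
#' truly changed.
#'
#' @param n_proteins number of proteins (default 1817).
#' @param n_per_group samples per group (default 4).
#' @param baseline_log_mean,baseline_log_sd natural-log location/spread of
#'   the lognormal baseline mean abundance (defaults 2.5 and 1.5; median
#'   count ~12 with a heavy right tail and many zeros at low abundance).
#' @param dispersion negative-binomial overdispersion phi, variance
#'   `mu + phi*mu^2` (default 0.3).
#' @param de_fraction fraction of proteins with a planted nonzero log2
#'   effect (default 0.08).
#' @param effect_log2_sd spread of planted log2 effects (default 1.5).
#' @param effect_size optional fixed magnitude: when non-`NULL`, every
#'   planted effect is `+effect_size` or `-effect_size` rather than
#'   half-normal with sd `effect_log2_sd`.
#' @param n_compartment number of compartment-annotated proteins
#'   (default 228; must not exceed `n_proteins`).
#' @param compartment_up_prob probability that a planted compartment
#'   effect is positive in the high group (default 0.75). Non-compartment
#'   effects are positive with probability 0.5.
#' @param n_regulators,targets_per_regulator size of the regulator network
#'   built by [simulate_regulator_network()] (defaults 8 and 10).
#' @param seed integer master seed; per-stage streams are derived from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 1817, n_per_group = 4,
                       baseline_log_mean = 2.5, baseline_log_sd = 1.5,
                       dispersion = 0.3, de_fraction = 0.08,
                       effect_log2_sd = 1.5, effect_size = NULL,
                       n_compartment = 228, compartment_up_prob = 0.75,
                       n_regulators = 8, targets_per_regulator = 10,
                       seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || !is.numeric(x) || !is.finite(x) || x < 1 || x != round(x))
      stop(nm, " must be a positive integer", call. = FALSE)
  }
  chk_prop <- function(x, nm) {
    if (length(x) != 1 || !is.numeric(x) || !is.finite(x) || x < 0 || x > 1)
      stop(nm, " must be a proportion in [0, 1]", call. = FALSE)
  }
  chk_pos <- function(x, nm) {
    if (length(x) != 1 || !is.numeric(x) || !is.finite(x) || x <= 0)
      stop(nm, " must be a positive real", call. = FALSE)
  }
  chk_count(n_proteins, "n_proteins"); chk_count(n_per_group, "n_per_group")
  chk_count(n_regulators, "n_regulators"); chk_count(targets_per_regulator, "targets_per_regulator")
  chk_pos(baseline_log_sd, "baseline_log_sd"); chk_pos(dispersion, "dispersion")
  chk_pos(effect_log2_sd, "effect_log2_sd")
  chk_prop(de_fraction, "de_fraction"); chk_prop(compartment_up_prob, "compartment_up_prob")
  if (!is.null(effect_size)) chk_pos(effect_size, "effect_size")
  if (length(n_compartment) != 1 || n_compartment < 0 || n_compartment != round(n_compartment))
    stop("n_compartment must be a non-negative integer", call. = FALSE)
  if (n_compartment > n_proteins)
    stop("n_compartment must not exceed n_proteins", call. = FALSE)
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed) ||
      abs(seed) > 2^31 - 100)
    stop("seed must be an integer below 2^31 - 100 in magnitude", call. = FALSE)

  structure(list(n_proteins = as.integer(n_proteins),
                 n_per_group = as.integer(n_per_group),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion, de_fraction = de_fraction,
                 effect_log2_sd = effect_log2_sd, effect_size = effect_size,
                 n_compartment = as.integer(n_compartment),
                 compartment_up_prob = compartment_up_prob,
                 n_regulators = as.integer(n_regulators),
                 targets_per_regulator = as.integer(targets_per_regulator),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic sub-stream: one master seed, fixed offsets per stage
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed + offset)
  expr
}

#' Simulate a spectral-count dataset with known ground truth
#'
#' Draws per-protein baseline mean abundances from a lognormal, plants
#' multiplicative log2 effects on the high group for a random subset of
#' proteins, and samples negative-binomial counts. The low group is the
#' reference: its per-protein mean equals the baseline, while the high
#' group's mean is `baseline * 2^effect`. Compartment membership is
#' assigned to a random subset of proteins; planted effects of compartment
#' members are positive with probability `compartment_up_prob`.
#'
#' All randomness derives from `config$seed`, so identical configurations
#' give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return A list of class `"pif_sim"` with elements
#'   \describe{
#'     \item{counts}{[count_matrix()] of integer spectral counts
#'       (all-zero proteins retained so the generator output is complete).}
#'     \item{truth}{data.frame with `protein`, `effect_log2` (0 for non-DE
#'       proteins), `compartment` (logical), `baseline_mean`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_proteins
  m <- config$n_per_group
  prot <- sprintf("P%05d", seq_len(n))
  samp <- c(sprintf("H%d", seq_len(m)), sprintf("L%d", seq_len(m)))
  groups <- stats::setNames(rep(c("high", "low"), each = m), samp)

  mu0 <- with_stream(config$seed, 0L,
                     rlnorm(n, config$baseline_log_mean, config$baseline_log_sd))

  n_de <- round(config$de_fraction * n)
  truth <- with_stream(config$seed, 1L, {
    comp <- rep(FALSE, n)
    comp[sample.int(n, config$n_compartment)] <- TRUE
    de <- sample.int(n, n_de)
    up_prob <- ifelse(comp, config$compartment_up_prob, 0.5)
    sgn <- ifelse(runif(n) < up_prob, 1, -1)
    eff <- rep(0, n)
    if (n_de > 0) {
      mag <- if (is.null(config$effect_size))
        abs(rnorm(n_de, 0, config$effect_log2_sd)) else rep(config$effect_size, n_de)
      eff[de] <- sgn[de] * mag
    }
    data.frame(protein = prot, effect_log2 = eff, compartment = comp,
               baseline_mean = mu0, stringsAsFactors = FALSE)
  })

  mu_high <- mu0 * 2^truth$effect_log2
  mu <- cbind(matrix(mu_high, n, m), matrix(mu0, n, m))
  counts <- with_stream(config$seed, 2L, {
    matrix(rnbinom(n * 2 * m, mu = as.vector(mu), size = 1 / config$dispersion),
           n, 2 * m, dimnames = list(prot, samp))
  })

  cm <- count_matrix(counts, groups, drop_all_zero = FALSE)
  structure(list(counts = cm, truth = truth, config = config), class = "pif_sim")
}

#' @export
print.pif_sim <- function(x, ...) {
  cat(sprintf("pif_sim: %d proteins x %d samples, %d planted effects, %d compartment members (seed %d)\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              sum(x$truth$effect_log2 != 0), sum(x$truth$compartment),
              x$config$seed))
  invisible(x)
}

#' Build a signed regulator-target network from planted effects
#'
#' Creates `n_regulators` regulators whose targets are drawn from the
#' proteins with nonzero planted effect. Each regulator has a true state
#' (alternating activated/inhibited). For a fraction `consistency` of its
#' edges the literature-expected regulation direction is set so that the
#' planted expression direction supports that state; the remaining edges
#' contradict it. With `consistency = 1` and all targets recovered in the
#' DE set, the downstream activation z-score is exactly
#' `state * sqrt(n_targets)`.
#'
#' @param truth the `truth` data.frame from [simulate_counts()] (or any
#'   data.frame with `protein` and `effect_log2`).
#' @param n_regulators,targets_per_regulator network size.
#' @param consistency proportion of edges agreeing with the regulator's
#'   true state (default 1).
#' @param seed integer seed.
#' @return data.frame of class `"regulator_network"` with columns
#'   `regulator`, `target`, `direction` (+1 regulator activates target,
#'   -1 represses); the regulators' true states are in
#'   `attr(, "true_state")`.
#' @export
simulate_regulator_network <- function(truth, n_regulators = 8,
                                       targets_per_regulator = 10,
                                       consistency = 1, seed = 1L) {
  if (consistency < 0 || consistency > 1)
    stop("consistency must be in [0, 1]", call. = FALSE)
  de <- truth[truth$effect_log2 != 0, , drop = FALSE]
  if (targets_per_regulator > nrow(de))
    stop("targets_per_regulator (", targets_per_regulator,
         ") exceeds the number of DE proteins (", nrow(de), ")", call. = FALSE)
  n_cons <- round(consistency * targets_per_regulator)
  with_stream(seed, 3L, {
    edges <- vector("list", n_regulators)
    state <- stats::setNames(rep_len(c(1, -1), n_regulators),
                             sprintf("REG%02d", seq_len(n_regulators)))
    for (r in seq_len(n_regulators)) {
      idx <- sample.int(nrow(de), targets_per_regulator)
      sgn <- sign(de$effect_log2[idx])
      agree <- rep(c(TRUE, FALSE), c(n_cons, targets_per_regulator - n_cons))
      # direction * observed sign = state for consistent edges
      dir <- ifelse(agree, state[r] * sgn, -state[r] * sgn)
      edges[[r]] <- data.frame(regulator = names(state)[r],
                               target = de$protein[idx],
                               direction = dir, stringsAsFactors = FALSE)
    }
    net <- do.call(rbind, edges)
    rownames(net) <- NULL
    structure(net, class = c("regulator_network", "data.frame"),
              true_state = state)
  })
}
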
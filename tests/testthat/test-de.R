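test_that("signed fold change follows the +/- magnitude->=1 convention", {
  mk <- function(h, l) {
    m <- matrix(c(rep(h, 4), rep(l, 4)), nrow = 1,
                dimnames = list("A", c("H1", "H2", "H3", "H4", "L1", "L2", "L3", "L4")))
    m <- rbind(m, B = rep(1, 8))  # companion row so the matrix is non-trivial
    count_matrix(m, toy_groups())
  }
  expect_equal(signed_fold_change(mk(2, 1), pseudo_count = 1e-9)[["A"]], 2,
               tolerance = 1e-6)
  expect_equal(signed_fold_change(mk(1, 2), pseudo_count = 1e-9)[["A"]], -2,
               tolerance = 1e-6)
  expect_equal(signed_fold_change(mk(3, 3))[["A"]], 1)
  # antisymmetry under group swap
  expect_equal(signed_fold_change(mk(5, 2), 1e-9)[["A"]],
               -signed_fold_change(mk(2, 5), 1e-9)[["A"]], tolerance = 1e-9)
  # pseudo-count keeps one-group-absent proteins finite
  expect_true(is.finite(signed_fold_change(mk(10, 0))[["A"]]))
})

test_that("variance prior: degenerate and boundary cases", {
  expect_error(fit_variance_prior(rep(0, 20), 6), "zero")
  pr <- fit_variance_prior(rep(2, 50), 6)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_2, 2, tolerance = 1e-9)
  # moderated variances collapse onto the common value
  mt <- moderated_t(c(0.5, -0.5), c(2, 2), pr$d0, pr$s0_2, 4, 4)
  expect_equal(mt$s2_tilde, c(2, 2))
  expect_error(fit_variance_prior(rep(1, 5), 6), "at least 10")
})

test_that("variance prior recovers known hyperparameters from scaled chi-square draws", {
  set.seed(101)
  d0_true <- 4; s0_true <- 1.2; d_g <- 6; n <- 5000
  sigma2 <- s0_true * d0_true / rchisq(n, d0_true)
  s2 <- sigma2 * rchisq(n, d_g) / d_g
  pr <- fit_variance_prior(s2, d_g)
  expect_lt(abs(pr$d0 - d0_true) / d0_true, 0.2)
  expect_lt(abs(pr$s0_2 - s0_true) / s0_true, 0.1)
})

test_that("variance prior agrees with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  s2 <- 0.8 * 5 / rchisq(2000, 5) * rchisq(2000, 6) / 6
  pr <- fit_variance_prior(s2, 6)
  sq <- limma::squeezeVar(s2, df = 6)
  expect_equal(pr$d0, sq$df.prior, tolerance = 0.01)
  expect_equal(pr$s0_2, sq$var.prior, tolerance = 0.01)
})

test_that("moderated t reduces to the pooled two-sample t at d0 = 0", {
  h <- c(3.1, 2.7, 3.4, 2.9); l <- c(2.0, 2.3, 1.8, 2.2)
  M <- mean(h) - mean(l)
  s2 <- ((3) * var(h) + (3) * var(l)) / 6
  mt <- moderated_t(M, s2, d0 = 0, s0_2 = 1, n_high = 4, n_low = 4)
  oracle <- t.test(h, l, var.equal = TRUE)
  expect_equal(mt$t_mod, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(mt$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(mt$df_total, 6)
})

test_that("moderated t null case, sentinel and shrinkage bounds", {
  mt <- moderated_t(0, 0.5, d0 = 4, s0_2 = 1, 4, 4)
  expect_equal(mt$t_mod, 0)
  expect_equal(mt$p, 1)

  expect_warning(mt0 <- moderated_t(1, 0, d0 = 0, s0_2 = 0, 4, 4), "zero moderated")
  expect_equal(mt0$p, 0)

  s2 <- c(0.1, 0.5, 2, 8)
  mt2 <- moderated_t(rep(1, 4), s2, d0 = 4, s0_2 = 1, 4, 4)
  expect_true(all(mt2$s2_tilde >= pmin(s2, 1) & mt2$s2_tilde <= pmax(s2, 1)))
  # moderation contracts the spread of variances
  expect_lt(var(mt2$s2_tilde), var(s2))
})

test_that("p is monotone in |M| at fixed variance and invariant under group swap", {
  Ms <- seq(0, 3, by = 0.25)
  mt <- moderated_t(Ms, rep(0.4, length(Ms)), d0 = 3, s0_2 = 0.5, 4, 4)
  expect_true(all(diff(mt$p) <= 1e-15))
  mt_neg <- moderated_t(-Ms, rep(0.4, length(Ms)), d0 = 3, s0_2 = 0.5, 4, 4)
  expect_equal(mt_neg$p, mt$p)
  expect_equal(mt_neg$t_mod, -mt$t_mod)
})

test_that("the DE filter applies the inclusive fold band and strict alpha", {
  de <- data.frame(protein = c("a", "b", "c", "d", "e"),
                   fold = c(1.25, 1.30, 16, -1.5, 2),
                   p = c(0.01, 0.049, 0.001, 0.02, 0.05))
  out <- de_filter(de, 1.3, 15, 0.05)
  expect_identical(out$protein, c("b", "d"))   # e excluded: p not < alpha
  expect_identical(attr(out, "n_up"), 1L)
  expect_identical(attr(out, "n_down"), 1L)
  expect_error(de_filter(de, 2, 1.5), "min_fold")
})

test_that("de_table is antisymmetric under group-label swap", {
  sim <- small_sim(250, seed = 51)
  nm <- normalize_total_counts(count_matrix(sim$counts$counts, sim$counts$groups))
  sw <- nm
  sw$groups <- setNames(ifelse(nm$groups == "high", "low", "high"), names(nm$groups))
  a <- suppressWarnings(de_table(nm)); b <- suppressWarnings(de_table(sw))
  expect_equal(b$fold, -a$fold, tolerance = 1e-9)
  expect_equal(b$t_mod, -a$t_mod, tolerance = 1e-9)
  expect_equal(b$p, a$p, tolerance = 1e-9)
})

test_that("planted strong effects at high abundance are recovered in sign", {
  sim <- simulate_counts(sim_config(n_proteins = 1500, effect_size = 2,
                                    de_fraction = 0.1, baseline_log_mean = 4.5,
                                    baseline_log_sd = 0.4, seed = 61))
  fit <- suppressMessages(pif_fit(sim$counts))
  truth <- sim$truth[match(fit$de$protein, sim$truth$protein), ]
  planted <- truth$effect_log2 != 0 & truth$baseline_mean >= 50
  expect_gt(sum(planted), 100)
  agree <- sign(fit$de$M[planted]) == sign(truth$effect_log2[planted])
  expect_gte(mean(agree), 0.95)
})

test_that("the whole moderated pipeline reproduces limma's eBayes p-values", {
  skip_if_not_installed("limma")
  sim <- simulate_counts(sim_config(n_proteins = 600, n_compartment = 100,
                                    seed = 179))
  fit <- suppressMessages(pif_fit(sim$counts))
  L <- log2(fit$normalized$counts + 0.05)
  design <- cbind(intercept = 1, high = fit$normalized$groups == "high")
  lf <- limma::eBayes(limma::lmFit(L, design))
  expect_equal(fit$prior$d0, lf$df.prior, tolerance = 1e-8)
  expect_equal(fit$prior$s0_2, lf$s2.prior, tolerance = 1e-8)
  expect_equal(unname(fit$de$p), unname(lf$p.value[, "high"]), tolerance = 1e-10)
  expect_equal(unname(fit$de$t_mod), unname(lf$t[, "high"]), tolerance = 1e-10)
})
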
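test_that("hypergeometric enrichment matches closed forms and exhaustive draws", {
  bg <- sprintf("G%02d", 1:20)
  terms <- list(hit5 = bg[1:5])
  res <- hypergeom_enrichment(bg[1:5], bg, terms)
  expect_equal(res$p_hyper, 1 / choose(20, 5), tolerance = 1e-12)

  # k = 0: upper tail is 1
  res0 <- hypergeom_enrichment(bg[6:10], bg, terms)
  expect_equal(res0$p_hyper, 1)
  expect_identical(res0$k, 0L)

  # N=10, K=5, n=4, k=4 against full enumeration of all C(10,4) draws
  bg10 <- sprintf("G%02d", 1:10)
  target <- bg10[1:4]
  draws <- utils::combn(10, 4)
  term_members <- 1:5
  k_obs <- 4
  enum <- mean(apply(draws, 2, function(d) sum(d %in% term_members) >= k_obs))
  res4 <- hypergeom_enrichment(target, bg10, list(tm = bg10[term_members]))
  expect_equal(res4$p_hyper, enum, tolerance = 1e-12)
  expect_equal(res4$p_hyper, 5 / 210, tolerance = 1e-12)

  # empty-in-background terms are skipped
  res_skip <- hypergeom_enrichment(bg[1:3], bg, list(absent = c("XX", "YY"),
                                                     hit5 = bg[1:5]))
  expect_identical(res_skip$term, "hit5")

  expect_error(hypergeom_enrichment(c(bg[1], "ALIEN"), bg, terms), "ALIEN")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.005, 0.009, 0.05, 0.5)
  expect_equal(bh_adjust(p), c(0.018, 0.018, 200 / 3000, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("activation z follows the consistency formula and its bounds", {
  net <- data.frame(regulator = rep("R", 15),
                    target = sprintf("T%02d", 1:15), direction = 1)
  obs_all_down <- setNames(rep(-1, 15), sprintf("T%02d", 1:15))
  z <- activation_z(net, obs_all_down)
  expect_equal(z$z, -15 / sqrt(15), tolerance = 1e-12)
  expect_equal(round(z$z, 3), -3.873)
  expect_identical(z$n_consistent_inhibition, 15L)

  net4 <- net[1:4, ]
  z4 <- activation_z(net4, obs_all_down)
  expect_equal(z4$z, -2.000, tolerance = 1e-12)

  mixed <- setNames(c(1, 1, 1, -1), sprintf("T%02d", 1:4))
  zm <- activation_z(net4, mixed)
  expect_equal(zm$z, (3 - 1) / 2)

  # antisymmetry and the sqrt(N) bound
  zf <- activation_z(net, -obs_all_down)
  expect_equal(zf$z, -z$z)
  expect_lte(abs(zm$z), sqrt(zm$n_informative))

  # non-informative targets: absent from the DE set
  z_part <- activation_z(net, obs_all_down[1:9])
  expect_identical(z_part$n_informative, 9L)
  z_none <- activation_z(net, setNames(numeric(0), character(0)))
  expect_true(is.na(z_none$z))
})

test_that("expected z tracks (2c-1)*sqrt(N) on synthetic networks", {
  sim <- small_sim(600, seed = 131, de_fraction = 0.5)
  observed <- setNames(sign(sim$truth$effect_log2), sim$truth$protein)
  observed <- observed[observed != 0]
  for (cons in c(0.5, 0.8)) {
    net <- simulate_regulator_network(sim$truth, n_regulators = 40,
                                      targets_per_regulator = 20,
                                      consistency = cons, seed = 137)
    z <- activation_z(net, observed)
    st <- attr(net, "true_state")[z$regulator]
    expected <- (2 * cons - 1) * sqrt(20)
    expect_equal(mean(z$z * st), expected, tolerance = 0.15 + 1e-9)
  }
})

test_that("overlap p equals the one-sided Fisher exact test on all small tables", {
  bg <- sprintf("B%02d", 1:12)
  for (nt in c(2, 5, 8)) for (nd in c(2, 6, 12)) {
    targets <- bg[seq_len(nt)]
    de <- bg[seq_len(nd)]
    p <- overlap_p(targets, de, bg)
    k <- length(intersect(targets, de))
    tab <- matrix(c(k, nt - k, nd - k, 12 - nt - nd + k), 2)
    expect_equal(p, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  # worked example: background 10, targets 5, DE 4, overlap 4
  bg10 <- sprintf("B%02d", 1:10)
  expect_equal(overlap_p(bg10[1:5], bg10[c(1:4)], bg10), 5 / 210,
               tolerance = 1e-12)
  # degenerate: everything overlaps everything
  expect_equal(overlap_p(bg10, bg10, bg10), 1)
  expect_error(overlap_p("a", "a", character(0)), "empty")
})

test_that("regulator classification applies the z and overlap-p bands", {
  expect_identical(classify_regulator(-3.873, 7.58e-11), "inhibited")
  expect_identical(classify_regulator(2.425, 4.29e-5), "activated")
  expect_identical(classify_regulator(1.954, 0.0455), "strong+")
  expect_identical(classify_regulator(-1.961, 1.49e-3), "strong-")
  expect_identical(classify_regulator(1.571, 1.18e-3), "moderate+")
  expect_identical(classify_regulator(1.2, 0.01), "weak+")
  expect_identical(classify_regulator(0.5, 0.001), "none")
  # |z| exactly at the activation threshold stays a qualified call
  expect_identical(classify_regulator(2.0, 0.001), "strong+")
  expect_identical(classify_regulator(-2.0, 0.001), "strong-")
  # insignificant overlap suppresses any call
  expect_identical(classify_regulator(3.5, 0.2), "none")
  expect_identical(classify_regulator(NA_real_, 0.001), "none")
  expect_error(classify_regulator(1, 0.01, bands = c(1, 2, 3)), "decreasing")
})

test_that("end-to-end regulator predictions recover planted states", {
  sim <- simulate_counts(sim_config(n_proteins = 700, effect_size = 2,
                                    de_fraction = 0.3, baseline_log_mean = 4,
                                    baseline_log_sd = 0.7, seed = 139))
  net <- simulate_regulator_network(sim$truth, n_regulators = 4,
                                    targets_per_regulator = 12,
                                    consistency = 1, seed = 139)
  fit <- suppressMessages(pif_fit(sim$counts))
  pred <- regulator_predictions(net, fit$de)
  st <- attr(net, "true_state")[pred$regulator]
  # planted effects are strong, so most informative targets agree with the state
  expect_true(all(sign(pred$z) == st))
  expect_true(all(pred$state[st == 1] %in% c("activated", "strong+")))
  expect_true(all(pred$state[st == -1] %in% c("inhibited", "strong-")))
})
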
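exact_tet <- function(rho, se = 1) {
  structure(list(rho = rho, se = se, boundary = FALSE),
            class = "tetrachoric")
}

test_that("AE and ACE weighted least squares solve the closed forms", {
  # null correlations: no additive variance
  f0 <- fit_ace_wls(list(full_sib = exact_tet(0), cousin = exact_tet(0)),
                    "AE")
  expect_equal(f0$a2, 0)

  # exactly model-consistent input: both residuals zero, a2 = 0.30
  f <- fit_ace_wls(list(full_sib = exact_tet(0.15),
                        cousin = exact_tet(0.0375)), "AE")
  expect_equal(f$a2, 0.30, tolerance = 1e-12)
  expect_equal(f$fit_statistic, 0, tolerance = 1e-20)
  expect_equal(f$df, 1L)
  expect_equal(f$e2, 0.70, tolerance = 1e-12)

  fc <- fit_ace_wls(list(full_sib = exact_tet(0.15),
                         cousin = exact_tet(0.0375)), "ACE")
  expect_equal(fc$a2, 8 * 0.0375, tolerance = 1e-12)
  expect_equal(fc$c2, 0.15 - 4 * 0.0375, tolerance = 1e-12)
  expect_equal(fc$df, 0L)

  # model-consistent grid leaves zero fit statistic and exact parameters
  for (a2 in c(0.1, 0.35, 0.6)) {
    for (c2 in c(0, 0.15)) {
      tabs <- list(full_sib = exact_tet(0.5 * a2 + c2),
                   cousin = exact_tet(0.125 * a2))
      g <- fit_ace_wls(tabs, "ACE")
      expect_equal(g$a2, a2, tolerance = 1e-10)
      expect_equal(g$c2, c2, tolerance = 1e-10)
      expect_lt(g$fit_statistic, 1e-18)
    }
  }
})

test_that("inadmissible correlation patterns hit flagged boundaries", {
  # cousin correlation above a quarter of the sibling one: c2 pinned at 0
  f <- fit_ace_wls(list(full_sib = exact_tet(0.10),
                        cousin = exact_tet(0.05)), "ACE")
  expect_true(f$boundary)
  expect_equal(f$c2, 0)
  expect_gte(f$a2, 0)
  # negative implied a2 collapses to a shared-environment-only solution
  g <- fit_ace_wls(list(full_sib = exact_tet(0.2),
                        cousin = exact_tet(-0.01)), "ACE")
  expect_true(g$boundary)
  expect_equal(g$a2, 0)
  expect_equal(g$c2, 0.2)
})

test_that("heritability is recovered from generated tables", {
  set.seed(601)
  tr <- list(trait_spec("d", 0.05, a2 = 0.4))
  fs <- simulate_pairs(3e5, "full_sib", tr)
  cz <- simulate_pairs(6e5, "cousin", tr)
  tabs <- list(full_sib = pair_crosstable(fs$a[, 1], fs$b[, 1], 2),
               cousin = pair_crosstable(cz$a[, 1], cz$b[, 1], 2))
  fit <- fit_ace_wls(tabs, "AE")
  se_a2 <- 1 / sqrt(sum(fit$weights * c(0.5, 0.125)^2))
  expect_lt(abs(fit$a2 - 0.4), 4 * se_a2)
  # the C component of the ACE fit on AE data is near zero
  ace <- fit_ace_wls(tabs, "ACE")
  cmp <- compare_models(ace, fit, df = 1L, boundary = ace$c2 <= 0)
  expect_gt(cmp$p_value, 0.01)
})

test_that("pair category probabilities are coherent and match simulation", {
  grid <- expand.grid(rg = c(-0.5, 0, 0.5, 0.82),
                      kin = c("full_sib", "cousin"),
                      excl = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    P <- pair_category_probs(grid$rg[i], c(0.3, 0.4),
                             c(qnorm(0.9), qnorm(0.8)), grid$kin[i],
                             exclusive = grid$excl[i])
    expect_equal(sum(P), 1, tolerance = 1e-8)
    expect_true(all(P >= 0))
    expect_equal(P, t(P), tolerance = 1e-12)
  }
  # against the generator at moderate prevalence
  set.seed(602)
  tr <- list(trait_spec("t1", 0.1, 0.3, wins = TRUE,
                        exclusive_with = "t2"),
             trait_spec("t2", 0.2, 0.4))
  rg <- matrix(c(1, 0.6, 0.6, 1), 2)
  n <- 1e6
  sim <- simulate_pairs(n, "full_sib", tr, rg = rg)
  emp <- pair_crosstable(sim$cat_a, sim$cat_b, 3) / n
  # calibrate z2 for the masked trait exactly as the fitter does
  z1 <- qnorm(0.9)
  rw <- 0.6 * sqrt(0.12)
  z2 <- famliab:::calibrate_z2_exclusive(
    pnorm(z1) - pbvn(z1, qnorm(0.8), rw), z1, rw)
  thr <- pair_category_probs(0.6, c(0.3, 0.4), c(z1, z2), "full_sib")
  expect_lt(max(abs(emp - thr)), 5 * sqrt(max(thr) / n))
})

test_that("ML genetic correlation recovers truth and is label-symmetric", {
  set.seed(603)
  tr <- list(trait_spec("t1", 0.05, 0.4, wins = TRUE,
                        exclusive_with = "t2"),
             trait_spec("t2", 0.08, 0.5))
  rg_true <- 0.5
  rg <- matrix(c(1, rg_true, rg_true, 1), 2)
  tabs <- list()
  for (k in c("full_sib", "cousin")) {
    sim <- simulate_pairs(4e5, k, tr, rg = rg)
    tabs[[k]] <- pair_crosstable(sim$cat_a, sim$cat_b, 3)
  }
  fit <- fit_rg_ml(tabs, a2 = c(0.4, 0.5), exclusive = TRUE)
  expect_lt(abs(fit$rg - rg_true), 0.1)
  expect_lt(fit$lrt_rg1$p_value, 0.01)
  expect_lt(fit$lrt_rg0$p_value, 0.01)

  # label-swap symmetry is exact for the non-exclusive model (the
  # exclusivity rule is directional: the winning trait masks the other, so
  # a strict swap would also have to swap the rule)
  set.seed(605)
  trn <- list(trait_spec("t1", 0.05, 0.4), trait_spec("t2", 0.08, 0.5))
  tabs4 <- list()
  for (k in c("full_sib", "cousin")) {
    sim <- simulate_pairs(3e5, k, trn, rg = rg, exclusive = FALSE)
    tabs4[[k]] <- pair_crosstable(sim$cat_a, sim$cat_b, 4)
  }
  fit4 <- fit_rg_ml(tabs4, a2 = c(0.4, 0.5), exclusive = FALSE)
  perm <- c(1L, 3L, 2L, 4L)  # none, t2, t1, both
  tabs_sw <- lapply(tabs4, function(m) m[perm, perm])
  fit_sw <- fit_rg_ml(tabs_sw, a2 = c(0.5, 0.4), exclusive = FALSE)
  expect_equal(fit_sw$rg, fit4$rg, tolerance = 1e-4)
  expect_lt(abs(fit4$rg - rg_true), 0.12)
})

test_that("likelihood-ratio machinery matches the chi-square reference", {
  f1 <- famliab:::new_liability_fit(model = "AE", estimator = "WLS",
                                    fit_statistic = 2.5)
  f2 <- famliab:::new_liability_fit(model = "AE", estimator = "WLS",
                                    fit_statistic = 2.5)
  expect_equal(compare_models(f1, f2)$p_value, 1)
  f3 <- famliab:::new_liability_fit(model = "ACE", estimator = "WLS",
                                    fit_statistic = 2.5 - 3.841459)
  cmp <- compare_models(f3, f1, df = 1L)
  expect_equal(cmp$p_value, 0.05, tolerance = 1e-5)
  cmp_b <- compare_models(f3, f1, df = 1L, boundary = TRUE)
  expect_equal(cmp_b$p_value_mixture, 0.025, tolerance = 1e-5)
})

test_that("family bootstrap is reproducible and degenerates to zero width", {
  # zero-variance statistic: constant across resamples
  fam <- rep(1:50, each = 2)
  out <- bootstrap_ci(function(w) c(k = 1.5), fam, n_boot = 50, seed = 1)
  expect_equal(unname(out$ci["k", ]), c(1.5, 1.5))
  # reproducibility
  stat <- function(w) c(m = sum(w * seq_along(w)) / sum(w))
  b1 <- bootstrap_ci(stat, fam, n_boot = 100, seed = 42)
  b2 <- bootstrap_ci(stat, fam, n_boot = 100, seed = 42)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(b1$ci["m", "lower"] <= b1$ci["m", "upper"])
})

test_that("rg difference test is calibrated at equality", {
  set.seed(604)
  b <- rnorm(400, 0, 0.05)
  same <- rg_difference_test(0.6 + b, 0.6 + b)
  expect_gt(same$p_value, 0.99)
  shifted <- rg_difference_test(0.67 + b, 0.46 + b)
  expect_lt(shifted$p_value, 0.01)
})
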
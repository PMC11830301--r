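test_that("pair simulator reproduces structural liability correlations", {
  set.seed(401)
  tr <- list(trait_spec("d", 0.1, a2 = 0.5, c2 = 0.2))
  n <- 4e5
  expected <- c(full_sib = 0.5 * 0.5 + 0.2, half_sib = 0.25 * 0.5,
                cousin = 0.125 * 0.5)
  for (k in names(expected)) {
    sim <- simulate_pairs(n, k, tr)
    est <- tetrachoric(pair_crosstable(sim$a[, 1], sim$b[, 1], 2))
    expect_lt(abs(est$rho - expected[k]), 5 * est$se)
    # prevalence recovery within binomial error
    phat <- mean(c(sim$a[, 1], sim$b[, 1]))
    expect_lt(abs(phat - 0.1), 5 * sqrt(0.1 * 0.9 / (2 * n)))
  }
})

test_that("no familial variance gives a null sibling correlation", {
  set.seed(402)
  tr <- list(trait_spec("d", 0.2, a2 = 0, c2 = 0))
  sim <- simulate_pairs(3e5, "full_sib", tr)
  est <- tetrachoric(pair_crosstable(sim$a[, 1], sim$b[, 1], 2))
  expect_lt(abs(est$rho), 4 * est$se)
})

test_that("concordance of a rare trait matches the orthant oracle", {
  set.seed(403)
  tr <- list(trait_spec("d", 0.002, a2 = 0.30))
  n <- 2.5e6
  sim <- simulate_pairs(n, "full_sib", tr)
  tab <- pair_crosstable(sim$a[, 1], sim$b[, 1], 2)
  z <- qnorm(1 - 0.002)
  # P(both affected) by numerical integration of the upper orthant at the
  # structural correlation 0.5 * a2 = 0.15
  p11 <- 1 - 2 * pnorm(z) + bvn_quad2(z, z, 0.15)
  expect_lt(abs(tab[2, 2] - n * p11), 5 * sqrt(n * p11))
})

test_that("cross-trait cross-sibling correlation follows 0.5 rg sqrt(a2 a2)", {
  set.seed(404)
  tr <- list(trait_spec("t1", 0.1, a2 = 0.3), trait_spec("t2", 0.1, a2 = 0.4))
  rg <- matrix(c(1, 0.82, 0.82, 1), 2)
  sim <- simulate_pairs(4e5, "full_sib", tr, rg = rg, exclusive = FALSE)
  est <- tetrachoric(pair_crosstable(sim$a[, 1], sim$b[, 2], 2))
  expect_lt(abs(est$rho - 0.5 * 0.82 * sqrt(0.3 * 0.4)), 5 * est$se)
})

test_that("exclusivity masking leaves no person with both diagnoses", {
  set.seed(405)
  tr <- list(trait_spec("psychotic_mdd", 0.05, 0.3, wins = TRUE,
                        exclusive_with = "non_psychotic_mdd"),
             trait_spec("non_psychotic_mdd", 0.2, 0.4))
  rg <- matrix(c(1, 0.8, 0.8, 1), 2)
  sim <- simulate_pairs(1e5, "full_sib", tr, rg = rg)
  expect_equal(sum(sim$a[, 1] * sim$a[, 2]), 0)
  expect_equal(sum(sim$b[, 1] * sim$b[, 2]), 0)
  expect_true(all(sim$cat_a %in% 0:2))
  # masking preserves the winner's marginal prevalence
  expect_lt(abs(mean(sim$a[, 1]) - 0.05), 5 * sqrt(0.05 * 0.95 / 1e5))
})

test_that("register generation is deterministic given the seed", {
  tr <- list(trait_spec("psychotic_mdd", 0.02, 0.3, wins = TRUE,
                        exclusive_with = "non_psychotic_mdd"),
             trait_spec("non_psychotic_mdd", 0.1, 0.4))
  cfg <- registry_config(150, tr, rg = matrix(c(1, .8, .8, 1), 2),
                         prs_specs = c(scz = log(1.3)), seed = 77L)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1, p2)
  # and writing produces byte-identical tables
  d1 <- file.path(tempdir(), "reg1"); d2 <- file.path(tempdir(), "reg2")
  write_registry(p1, d1); write_registry(p2, d2)
  for (f in c("persons.tsv", "diagnoses.tsv", "prs.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("generated pedigrees have consistent links and kinship counts", {
  tr <- list(trait_spec("d", 0.1, 0.4))
  cfg <- registry_config(80, tr, p_extra_halfsib = 0.5, seed = 3L)
  pop <- simulate_population(cfg)
  pp <- pop$persons
  # parent ids resolve; generation-2 children have both parents in-table
  expect_true(all(is.na(pp$father_id) | pp$father_id %in% pp$person_id))
  kids <- pp[pp$generation == 2L, ]
  expect_true(all(!is.na(kids$father_id) & !is.na(kids$mother_id)))
  # template closed form (no birth-gap filter): per family, full-sib pairs
  # = C(s1,2) + C(s2,2) + 1 (linking sibs), cousin pairs = (s1 + extra) * s2
  pairs <- extract_pairs(pp, max_birth_gap = Inf)
  sibship <- paste(pp$father_id, pp$mother_id)
  per_couple <- table(sibship[pp$generation >= 1 & !is.na(pp$father_id)])
  expect_equal(sum(pairs$kinship == "full_sib"),
               sum(choose(as.vector(per_couple), 2)))
  # half-sib pairs exist exactly in families with an extra-partner child
  hs <- pairs[pairs$kinship == "half_sib", ]
  with_extra <- length(unique(hs$family_id))
  expect_gt(with_extra, 0)
  expect_true(all(table(hs$family_id) >= 1))
})

test_that("invalid cross-trait correlation inputs are rejected by name", {
  tr2 <- list(trait_spec("a", 0.1, 1, c2 = 0), trait_spec("b", 0.1, 1))
  bad <- matrix(c(1, 1.5, 1.5, 1), 2)
  expect_error(famliab:::pair_liability_cov(tr2, "full_sib", rg = bad),
               "positive semidefinite")
  expect_error(registry_config(10, tr2, rg = bad),
               "positive semidefinite")
})

test_that("aggregation-pair generator hits its odds ratio at scale", {
  set.seed(406)
  ap <- simulate_aggregation_pairs(4e5, 0.05, 2.5)
  tab <- table(ap$y_a, ap$y_b)
  or_hat <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  woolf <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or_hat) - log(2.5)), 4 * woolf)
})

test_that("case-case PRS generator recovers nulls and guards degeneracy", {
  set.seed(407)
  cc <- simulate_prs_casecase(20000, c(s1 = 0, s2 = 0), p_psychotic = 0.3)
  fits <- fit_prs_models(cc, c("s1", "s2"), mode = "univariate")
  for (f in fits) {
    expect_lt(abs(f$log_or), 4 * f$robust_se)
    expect_true(f$ci_low < 1 && f$ci_high > 1)
  }
  expect_warning(
    expect_error(simulate_prs_casecase(30, c(s = 0), p_psychotic = 1e-9,
                                       max_retry = 2L),
                 "failed to generate"),
    "degenerate")
})
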
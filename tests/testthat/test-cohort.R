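test_that("ICD normalisation uppercases and dot-normalises", {
  expect_equal(normalize_icd(c("f323", "F32.3", " f20")),
               c("F32.3", "F32.3", "F20"))
  expect_error(normalize_icd(c("F32.3", "??")), "\\?\\?")
})

test_that("MDD classification covers every branch under both definitions", {
  persons <- toy_persons6()
  dx <- toy_diagnoses()
  cs <- default_codesets()

  main <- classify_mdd(persons, dx, cs, "main")
  expect_equal(as.character(main$label),
               c("non_psychotic_mdd",  # F32.1 only
                 "psychotic_mdd",      # F33.3 + F20 (no exclusion, main)
                 "psychotic_mdd",      # F32.3 only
                 "non_psychotic_mdd",  # F33.0 + F30 (BD kept, main)
                 "non_psychotic_mdd",  # F32.9 + F25
                 "none"))              # no codes

  restr <- classify_mdd(persons, dx, cs, "restrictive")
  expect_equal(as.character(restr$label),
               c("non_psychotic_mdd",
                 "none",               # psychotic + SCZ -> dropped entirely
                 "psychotic_mdd",
                 "none",               # BD removes from all MDD
                 "non_psychotic_mdd",  # SAD only bars psychotic MDD
                 "none"))

  # labels partition the cohort and restrictive sets nest in main sets
  expect_true(all(table(main$person_id) == 1))
  r_psych <- restr$person_id[restr$label == "psychotic_mdd"]
  m_psych <- main$person_id[main$label == "psychotic_mdd"]
  expect_true(all(r_psych %in% m_psych))
  r_mdd <- restr$person_id[restr$label != "none"]
  m_mdd <- main$person_id[main$label != "none"]
  expect_true(all(r_mdd %in% m_mdd))
})

test_that("eligibility removes early-censored and out-of-window persons", {
  pp <- data.frame(person_id = 1:10, family_id = 1,
                   sex = "F", birth_year = c(rep(1970L, 8), 1940L, 1995L),
                   father_id = NA, mother_id = NA,
                   age_at_death_or_emigration =
                     c(19, 19.9, 20, 25, NA, NA, 3, 60, NA, NA))
  out <- apply_eligibility(pp, birth_window = c(1958L, 1993L))
  # hand trace: 1, 2, 7 censored before 20; 9, 10 outside window
  expect_equal(out$person_id, c(3L, 4L, 5L, 6L, 8L))
  expect_equal(attr(out, "n_removed"), 5L)
  # no birth window: only censoring applies
  out2 <- apply_eligibility(pp)
  expect_equal(nrow(out2), 7L)
})

test_that("pair extraction classifies the hand-built pedigree", {
  ped <- toy_pedigree()
  pairs <- extract_pairs(ped, max_birth_gap = 10)
  key <- function(k) {
    s <- pairs[pairs$kinship == k, c("person_a", "person_b")]
    s <- s[order(s$person_a, s$person_b), ]
    unname(apply(s, 1, paste, collapse = "-"))
  }
  # full sibs: linking sibs (3, 5); sibship one (7, 8); sibship two (9, 10)
  expect_equal(key("full_sib"), c("3-5", "7-8", "9-10"))
  # 11 shares only mother 3 with 7 and 8; born within 10 years of both
  expect_equal(key("half_sib"), c("7-11", "8-11"))
  # cousins: children of 3 x children of 6 (11 included via mother 3)
  expect_equal(key("cousin"),
               c("7-9", "7-10", "8-9", "8-10", "9-11", "10-11"))
  expect_equal(pairs$a_share[pairs$kinship == "cousin"][1], 0.125)

  # widening the sibling birth-gap filter admits an 11-year-apart sib pair
  ped2 <- ped
  ped2$birth_year[8] <- 1995L  # 7 born 1984, 8 born 1995
  p10 <- extract_pairs(ped2, max_birth_gap = 10)
  expect_false("7-8" %in% unname(apply(
    p10[, c("person_a", "person_b")], 1, paste, collapse = "-")))
  pInf <- extract_pairs(ped2, max_birth_gap = Inf)
  expect_equal(sum(pInf$kinship == "full_sib"), 3L)
  # cousin pairs are unaffected by the sibling birth-gap filter
  expect_equal(sum(p10$kinship == "cousin"), 6L)

  # idempotent and unordered-unique
  expect_identical(pairs, extract_pairs(ped, max_birth_gap = 10))
  expect_true(all(pairs$person_a < pairs$person_b))
  expect_error(extract_pairs(data.frame(
    person_id = 1:2, family_id = 1, birth_year = 1970L,
    father_id = c(2L, 1L), mother_id = NA_integer_)), "cycle")
})

test_that("conversion table reproduces a hand-computed toy cohort", {
  # 8 persons: 4 psychotic MDD (ids 1-4), 4 non-psychotic (ids 5-8)
  labels <- data.frame(
    person_id = 1:8,
    label = factor(rep(c("psychotic_mdd", "non_psychotic_mdd"), each = 4),
                   levels = c("none", "non_psychotic_mdd",
                              "psychotic_mdd")))
  dx <- data.frame(
    person_id = c(1:8, 1, 2, 3, 5),
    code = c(rep("F32.3", 4), rep("F32.1", 4),
             "F31", "F31", "F20", "F22"),
    age = c(30, 30, 30, 30, 30, 30, 30, 30,
            25,   # person 1: BD before first MDD
            30,   # person 2: BD tied -> counts as before
            35,   # person 3: SCZ after
            40))  # person 5: other psychotic after
  ct <- conversion_table(labels, dx)
  row <- function(st, g) ct[ct$subtype == st & ct$disorder == g, ]
  expect_equal(row("psychotic_mdd", "bd")$p_before, 2 / 4)
  expect_equal(row("psychotic_mdd", "bd")$p_after, 0)
  expect_equal(row("psychotic_mdd", "scz_sad")$p_after, 1 / 4)
  expect_equal(row("psychotic_mdd", "other_psychotic")$p_any, 0)
  expect_equal(row("non_psychotic_mdd", "other_psychotic")$p_after, 1 / 4)
  # tie handling is configurable
  ct2 <- conversion_table(labels, dx, tie = "after")
  expect_equal(ct2[ct2$subtype == "psychotic_mdd" &
                     ct2$disorder == "bd", "p_before"], 1 / 4)
  # missing ages excluded with a warning
  dx$age[9] <- NA
  expect_warning(conversion_table(labels, dx), "missing age")
})

test_that("generator conversion probabilities are recovered", {
  tr <- list(trait_spec("psychotic_mdd", 0.02, 0.3, wins = TRUE,
                        exclusive_with = "non_psychotic_mdd"),
             trait_spec("non_psychotic_mdd", 0.08, 0.4))
  cfg <- registry_config(2500, tr, rg = matrix(c(1, .8, .8, 1), 2),
                         seed = 11L)
  pop <- simulate_population(cfg)
  labels <- classify_mdd(pop$persons, pop$diagnoses)
  ct <- conversion_table(labels, pop$diagnoses)
  truth <- cfg$conversion$psychotic_mdd
  for (g in c("scz_sad", "bd", "other_psychotic")) {
    row <- ct[ct$subtype == "psychotic_mdd" & ct$disorder == g, ]
    p <- truth[[sub("other_psychotic", "other_psych", g)]]
    expect_lt(abs(row$p_any - p), 5 * sqrt(p * (1 - p) / row$n_cases),
              label = paste("conversion", g))
  }
})

test_that("descriptive summary counts a hand-traced fixture", {
  pp <- data.frame(person_id = 1:20, family_id = 1,
                   sex = rep(c("F", "M"), 10), birth_year = 1970L,
                   father_id = NA, mother_id = NA,
                   age_at_death_or_emigration = NA_real_)
  labels <- data.frame(person_id = 1:20,
                       label = factor(c(rep("psychotic_mdd", 2),
                                        rep("non_psychotic_mdd", 6),
                                        rep("none", 12)),
                                      levels = c("none",
                                                 "non_psychotic_mdd",
                                                 "psychotic_mdd")))
  d <- descriptives(pp, labels)
  expect_equal(d$n_total, 20)
  expect_equal(d$pct_female, 50)
  expect_equal(d$n_mdd, 8)
  expect_equal(d$pct_psychotic_in_mdd, 100 * 2 / 8)
  expect_equal(d$pct_psychotic_in_pop, 10)
  # empty cohort: zero counts, null percentages
  e <- descriptives(pp[0, ], labels[0, ])
  expect_equal(e$n_total, 0)
  expect_true(is.na(e$pct_psychotic_in_mdd))
})
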
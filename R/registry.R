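## Synthetic population-register generator.
##
## Families follow a fixed three-generation template: a grandparental couple,
## two of their children ("linking" full siblings) who each marry an unrelated
## founder spouse, and the two resulting sibships. Children within a sibship
## are full siblings; children across the two sibships are first cousins
## (their linking parents are full siblings). Optionally a mother has further
## children with a second partner, creating maternal half-siblings.
##
## Binary diagnoses arise from a multivariate liability-threshold model:
## per-person liability l_t = g_t + c_t + e_t with Var = a2 + c2 + e2 = 1.
## Genetic values are transmitted (child = midparent + Mendelian deviation),
## which yields the classical expected liability correlations
## 0.5*a2 + c2 (full sibs), 0.25*a2 + kappa*c2 (half sibs), 0.125*a2 (cousins).

#' Specify a liability-threshold trait
#'
#' @param name trait label (used as column/code-set key).
#' @param prevalence lifetime prevalence in (0, 1); the diagnostic threshold
#'   is `qnorm(1 - prevalence)` on the standard-normal liability scale.
#' @param a2,c2 additive-genetic and shared-environment liability variance
#'   shares in \[0, 1\]; the unique-environment share is `1 - a2 - c2`.
#' @param exclusive_with optional name of a trait that cannot co-occur with
#'   this one in the same person.
#' @param wins if `TRUE` this trait takes precedence when both members of an
#'   exclusive pair fire (e.g. any psychotic code makes the person psychotic).
#' @param codes character vector of ICD-10 codes emitted for this trait.
#' @return a `trait_spec` list with the derived `threshold`.
#' @export
trait_spec <- function(name, prevalence, a2, c2 = 0, exclusive_with = NULL,
                       wins = FALSE, codes = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            prevalence > 0, prevalence < 1,
            a2 >= 0, a2 <= 1, c2 >= 0, c2 <= 1, a2 + c2 <= 1 + 1e-12)
  e2 <- 1 - a2 - c2
  if (e2 < 0) e2 <- 0
  stopifnot(abs(a2 + c2 + e2 - 1) < 1e-12)
  structure(list(name = name, prevalence = prevalence,
                 a2 = a2, c2 = c2, e2 = e2,
                 threshold = stats::qnorm(1 - prevalence),
                 exclusive_with = exclusive_with, wins = isTRUE(wins),
                 codes = codes %||% name),
            class = "trait_spec")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## kinship -> expected additive / shared-environment sharing
kinship_shares <- function(kinship, kappa_half = 0) {
  switch(kinship,
         full_sib = list(a = 0.5,   c = 1),
         half_sib = list(a = 0.25,  c = kappa_half),
         cousin   = list(a = 0.125, c = 0),
         stop("unknown kinship class: ", kinship))
}

## Assemble the 2T x 2T pair liability correlation matrix for a list of
## traits with genetic (rg), shared-env (rc) and unique-env (re) cross-trait
## correlation matrices. Errors if the implied matrix is not PSD.
pair_liability_cov <- function(traits, kinship, rg = NULL, rc = NULL,
                               re = NULL, kappa_half = 0) {
  tn <- length(traits)
  id <- diag(1, tn)
  rg <- rg %||% id; rc <- rc %||% id; re <- re %||% id
  stopifnot(isSymmetric(unname(rg)), isSymmetric(unname(rc)),
            isSymmetric(unname(re)))
  sa <- sqrt(vapply(traits, `[[`, numeric(1), "a2"))
  sc <- sqrt(vapply(traits, `[[`, numeric(1), "c2"))
  se <- sqrt(vapply(traits, `[[`, numeric(1), "e2"))
  W <- rg * tcrossprod(sa) + rc * tcrossprod(sc) + re * tcrossprod(se)
  diag(W) <- 1
  sh <- kinship_shares(kinship, kappa_half)
  B <- sh$a * rg * tcrossprod(sa) + sh$c * rc * tcrossprod(sc)
  S <- rbind(cbind(W, B), cbind(B, W))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("implied pair liability covariance is not positive semidefinite ",
         "(min eigenvalue ", format(min(ev), digits = 4),
         "); offending blocks: within-person ",
         paste(round(W[upper.tri(W, diag = TRUE)], 4), collapse = ", "),
         "; cross-person ",
         paste(round(B[upper.tri(B, diag = TRUE)], 4), collapse = ", "))
  }
  list(S = S, W = W, B = B)
}

#' Simulate relative pairs directly from the joint liability model
#'
#' Draws `n_pairs` relative pairs of the given kinship class from the exact
#' joint normal implied by the trait variance shares and cross-trait
#' correlations, thresholds the liabilities, and (optionally) applies the
#' mutual-exclusivity rule. This is the vectorised workhorse behind
#' [simulate_population()] pair checks and is convenient when only pair
#' phenotypes (not the full register) are needed.
#'
#' @param n_pairs number of pairs.
#' @param kinship one of `"full_sib"`, `"half_sib"`, `"cousin"`.
#' @param traits list of [trait_spec()] objects.
#' @param rg,rc,re optional cross-trait correlation matrices for the genetic,
#'   shared-environment and unique-environment components (default identity).
#' @param kappa_half shared-environment sharing for half siblings.
#' @param exclusive apply the exclusivity rule encoded in the traits
#'   (first trait with `wins = TRUE` masks its partner).
#' @param chunk pairs simulated per block, to bound memory.
#' @return list with integer matrices `a`, `b` (n_pairs x traits, 0/1
#'   affection after any exclusivity masking) and, when exactly two traits
#'   are supplied, integer category vectors `cat_a`, `cat_b`
#'   (0 = unaffected, 1 = trait 1, 2 = trait 2, 3 = both; 3 cannot occur
#'   under exclusivity).
#' @export
simulate_pairs <- function(n_pairs, kinship, traits, rg = NULL, rc = NULL,
                           re = NULL, kappa_half = 0, exclusive = TRUE,
                           chunk = 1e6) {
  stopifnot(n_pairs >= 1)
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  tn <- length(traits)
  cov <- pair_liability_cov(traits, kinship, rg, rc, re, kappa_half)
  L <- chol(cov$S + diag(1e-12, 2 * tn))
  z <- vapply(traits, `[[`, numeric(1), "threshold")
  a <- matrix(0L, n_pairs, tn)
  b <- matrix(0L, n_pairs, tn)
  done <- 0
  while (done < n_pairs) {
    m <- min(chunk, n_pairs - done)
    liab <- matrix(stats::rnorm(m * 2 * tn), m, 2 * tn) %*% L
    idx <- (done + 1):(done + m)
    a[idx, ] <- t(t(liab[, seq_len(tn), drop = FALSE]) > z) + 0L
    b[idx, ] <- t(t(liab[, tn + seq_len(tn), drop = FALSE]) > z) + 0L
    done <- done + m
  }
  if (exclusive) {
    a <- apply_exclusivity(a, traits)
    b <- apply_exclusivity(b, traits)
  }
  colnames(a) <- colnames(b) <- vapply(traits, `[[`, character(1), "name")
  out <- list(a = a, b = b, kinship = kinship)
  if (tn == 2L) {
    out$cat_a <- a[, 1L] + 2L * a[, 2L]
    out$cat_b <- b[, 1L] + 2L * b[, 2L]
  }
  out
}

## mask the losing trait of each exclusive pair when both fire
apply_exclusivity <- function(status, traits) {
  nm <- vapply(traits, `[[`, character(1), "name")
  for (i in seq_along(traits)) {
    ex <- traits[[i]]$exclusive_with
    if (is.null(ex) || !traits[[i]]$wins) next
    j <- match(ex, nm)
    if (is.na(j)) next
    status[, j] <- status[, j] * (1L - status[, i])
  }
  status
}

#' Generator configuration for the synthetic register
#'
#' @param n_families number of three-generation family templates.
#' @param traits list of [trait_spec()] objects.
#' @param rg,rc,re cross-trait correlation matrices (genetic, shared-env,
#'   unique-env); default identity.
#' @param kappa_half shared-environment correlation granted to half-siblings
#'   (the full-sib/cousin contrast leaves it unidentified; default 0).
#' @param p_extra_halfsib probability that a family's first sibship gains an
#'   extra child by a second partner (creating maternal half-sib pairs).
#' @param offspring_probs probability vector over sibship sizes 1, 2, ....
#' @param birth_year_range two integers; study birth window for generation-2
#'   children.
#' @param followup_end calendar year at which follow-up is administratively
#'   censored.
#' @param censor_prob probability of death/emigration censoring at a uniform
#'   age in \[0, 60\].
#' @param onset_range age window (years) over which first diagnoses occur.
#' @param conversion named list per MDD subtype label with elements
#'   `scz_sad`, `bd`, `other_psych` (comorbidity probabilities) and
#'   `p_before` (probability the comorbid code predates the first MDD code).
#' @param treatment named list per subtype with `antipsychotic` and `ect`
#'   probabilities.
#' @param prs_specs named numeric vector of per-SD log odds ratios for the
#'   psychotic-vs-non-psychotic case contrast, one per score column, plus
#'   attribute-free pairwise correlation `prs_cor` between score columns.
#' @param prs_cor common pairwise correlation between polygenic score columns.
#' @param seed integer seed; the whole register is deterministic given it.
#' @return a `registry_config` list.
#' @export
registry_config <- function(n_families,
                            traits,
                            rg = NULL, rc = NULL, re = NULL,
                            kappa_half = 0,
                            p_extra_halfsib = 0.15,
                            offspring_probs = c(0.25, 0.45, 0.25, 0.05),
                            birth_year_range = c(1958L, 1993L),
                            followup_end = 2013L,
                            censor_prob = 0.03,
                            onset_range = c(18, 45),
                            conversion = list(
                              psychotic_mdd = list(scz_sad = 0.159, bd = 0.174,
                                                   other_psych = 0.219,
                                                   p_before = 0.3),
                              non_psychotic_mdd = list(scz_sad = 0.02, bd = 0.04,
                                                       other_psych = 0.04,
                                                       p_before = 0.3)),
                            treatment = list(
                              psychotic_mdd = list(antipsychotic = 0.7386,
                                                   ect = 0.1465),
                              non_psychotic_mdd = list(antipsychotic = 0.2392,
                                                       ect = 0.0186)),
                            prs_specs = NULL,
                            prs_cor = 0.3,
                            seed = 1L) {
  stopifnot(n_families >= 1, length(traits) >= 1,
            abs(sum(offspring_probs) - 1) < 1e-8)
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  tn <- length(traits)
  chk <- function(m) {
    if (is.null(m)) return(diag(1, tn))
    stopifnot(isSymmetric(unname(m)), nrow(m) == tn)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("cross-trait correlation matrix is not positive semidefinite")
    m
  }
  structure(list(n_families = as.integer(n_families), traits = traits,
                 rg = chk(rg), rc = chk(rc), re = chk(re),
                 kappa_half = kappa_half,
                 p_extra_halfsib = p_extra_halfsib,
                 offspring_probs = offspring_probs,
                 birth_year_range = as.integer(birth_year_range),
                 followup_end = as.integer(followup_end),
                 censor_prob = censor_prob,
                 onset_range = onset_range,
                 conversion = conversion, treatment = treatment,
                 prs_specs = prs_specs, prs_cor = prs_cor,
                 seed = as.integer(seed)),
            class = "registry_config")
}

## default ICD-10 codes emitted per generator trait name
.default_trait_codes <- list(
  psychotic_mdd      = c("F32.3", "F33.3"),
  non_psychotic_mdd  = c("F32.0", "F32.1", "F32.2", "F33.0", "F33.1", "F33.2"),
  scz_sad            = c("F20", "F25"),
  bd                 = c("F31.0", "F31.1", "F31.2"),
  other_psychotic    = c("F22", "F23", "F28", "F29")
)

#' Simulate a register-shaped population with pedigree structure
#'
#' Generates persons, diagnosis events (ICD-10 codes with ages), treatment
#' events and polygenic-score columns under the liability-threshold model of
#' the configuration, with ground truth echoed back for validation of every
#' downstream estimator.
#'
#' @param config a [registry_config()].
#' @return list with data frames `persons`, `diagnoses`, `treatments`, `prs`
#'   and a `truth` list echoing the generating parameters.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  set.seed(config$seed)
  traits <- config$traits
  tn <- length(traits)
  nm <- vapply(traits, `[[`, character(1), "name")
  nf <- config$n_families

  ## --- family template sizes -------------------------------------------
  sizes1 <- sample.int(length(config$offspring_probs), nf, replace = TRUE,
                       prob = config$offspring_probs)
  sizes2 <- sample.int(length(config$offspring_probs), nf, replace = TRUE,
                       prob = config$offspring_probs)
  extra <- stats::rbinom(nf, 1L, config$p_extra_halfsib)

  ## per-family person layout:
  ## gp-father, gp-mother, link1 (child of gps), spouse1, link2 (child of
  ## gps), spouse2, [spouse1b], sibship1 children (incl. possibly one by
  ## spouse1b), sibship2 children
  n_per_fam <- 6L + extra + sizes1 + extra + sizes2
  total <- sum(n_per_fam)
  fam_of <- rep.int(seq_len(nf), n_per_fam)
  pid <- seq_len(total)
  off <- c(0L, cumsum(n_per_fam))  # family offsets

  gpf <- off[seq_len(nf)] + 1L
  gpm <- gpf + 1L
  link1 <- gpf + 2L
  sp1 <- gpf + 3L
  link2 <- gpf + 4L
  sp2 <- gpf + 5L
  sp1b <- ifelse(extra == 1L, gpf + 6L, NA_integer_)
  kid_start1 <- gpf + 6L + extra
  kid_start2 <- kid_start1 + sizes1 + extra

  father <- mother <- rep(NA_integer_, total)
  generation <- rep(2L, total)
  generation[c(gpf, gpm, sp1, sp2, sp1b[!is.na(sp1b)])] <- 0L
  generation[c(link1, link2)] <- 1L
  generation[c(sp1, sp2, sp1b[!is.na(sp1b)])] <- 1L
  father[c(link1, link2)] <- gpf
  mother[c(link1, link2)] <- gpm

  ## sibship children parents; link1 is the mother of sibship 1 and link2
  ## the father of sibship 2 (so the linking full sibs differ in sex)
  kids1 <- unlist(lapply(seq_len(nf), function(f)
    kid_start1[f] + seq_len(sizes1[f]) - 1L), use.names = FALSE)
  kids1_fam <- rep.int(seq_len(nf), sizes1)
  mother[kids1] <- link1[kids1_fam]
  father[kids1] <- sp1[kids1_fam]
  ## extra half-sib child: mother link1, father sp1b
  hkids <- (kid_start1 + sizes1)[extra == 1L]
  hfam <- which(extra == 1L)
  mother[hkids] <- link1[hfam]
  father[hkids] <- sp1b[hfam]
  kids2 <- unlist(lapply(seq_len(nf), function(f)
    kid_start2[f] + seq_len(sizes2[f]) - 1L), use.names = FALSE)
  kids2_fam <- rep.int(seq_len(nf), sizes2)
  father[kids2] <- link2[kids2_fam]
  mother[kids2] <- sp2[kids2_fam]

  sex <- sample(c("F", "M"), total, replace = TRUE)
  sex[link1] <- "F"; sex[sp1] <- "M"; sex[sp1b[!is.na(sp1b)]] <- "M"
  sex[link2] <- "M"; sex[sp2] <- "F"
  sex[gpf] <- "M"; sex[gpm] <- "F"

  ## --- birth years ------------------------------------------------------
  yr <- config$birth_year_range
  base <- sample(seq(yr[1L], max(yr[1L], yr[2L] - 8L)), nf, replace = TRUE)
  birth <- rep(NA_integer_, total)
  birth[gpf] <- base - 52L; birth[gpm] <- base - 50L
  birth[link1] <- base - 26L; birth[link2] <- base - 24L
  birth[sp1] <- base - 27L; birth[sp2] <- base - 25L
  birth[sp1b[!is.na(sp1b)]] <- base[extra == 1L] - 23L
  gaps1 <- sample(c(1L, 2L, 3L, 4L, 12L), length(kids1), replace = TRUE,
                  prob = c(0.30, 0.30, 0.20, 0.15, 0.05))
  o1 <- stats::ave(gaps1, kids1_fam, FUN = function(g) cumsum(g) - g[1L])
  birth[kids1] <- base[kids1_fam] + o1
  birth[hkids] <- birth[(kid_start1 + sizes1 - 1L)[extra == 1L]] +
    sample(2:6, length(hkids), replace = TRUE)
  gaps2 <- sample(c(1L, 2L, 3L, 4L, 12L), length(kids2), replace = TRUE,
                  prob = c(0.30, 0.30, 0.20, 0.15, 0.05))
  o2 <- stats::ave(gaps2, kids2_fam, FUN = function(g) cumsum(g) - g[1L])
  birth[kids2] <- base[kids2_fam] + 2L + o2

  censored <- stats::runif(total) < config$censor_prob
  cens_age <- ifelse(censored, round(stats::runif(total, 0, 60), 1), NA_real_)

  ## --- liabilities by transmission -------------------------------------
  sa <- sqrt(vapply(traits, `[[`, numeric(1), "a2"))
  sc <- sqrt(vapply(traits, `[[`, numeric(1), "c2"))
  se <- sqrt(vapply(traits, `[[`, numeric(1), "e2"))
  Acov <- config$rg * tcrossprod(sa)
  Ccov <- config$rc * tcrossprod(sc)
  Ecov <- config$re * tcrossprod(se)
  rmvn <- function(n, S) {
    if (all(S == 0)) return(matrix(0, n, tn))
    matrix(stats::rnorm(n * tn), n, tn) %*% chol(S + diag(1e-12, tn))
  }
  g <- matrix(0, total, tn)
  founders <- which(is.na(father))
  g[founders, ] <- rmvn(length(founders), Acov)
  gen1kids <- c(link1, link2)
  g[gen1kids, ] <- 0.5 * (g[father[gen1kids], , drop = FALSE] +
                            g[mother[gen1kids], , drop = FALSE]) +
    rmvn(length(gen1kids), Acov / 2)
  gen2 <- which(generation == 2L)
  g[gen2, ] <- 0.5 * (g[father[gen2], , drop = FALSE] +
                        g[mother[gen2], , drop = FALSE]) +
    rmvn(length(gen2), Acov / 2)

  ## shared environment: couple-level + mother-level components so that
  ## full sibs correlate 1 and maternal half sibs kappa_half
  couple_key <- ifelse(is.na(father), NA,
                       paste(fam_of, father, mother, sep = "_"))
  ck <- factor(couple_key, exclude = NA)
  mk <- factor(ifelse(is.na(mother), NA, paste(fam_of, mother, sep = "_")),
               exclude = NA)
  c_couple <- rmvn(nlevels(ck), Ccov)
  c_mother <- rmvn(nlevels(mk), Ccov)
  cenv <- matrix(0, total, tn)
  has_par <- !is.na(father)
  kap <- config$kappa_half
  cenv[has_par, ] <- sqrt(1 - kap) * c_couple[as.integer(ck[has_par]), ,
                                              drop = FALSE] +
    sqrt(kap) * c_mother[as.integer(mk[has_par]), , drop = FALSE]
  cenv[!has_par, ] <- rmvn(sum(!has_par), Ccov)

  liab <- g + cenv + rmvn(total, Ecov)

  z <- vapply(traits, `[[`, numeric(1), "threshold")
  status <- t(t(liab) > z) + 0L
  status <- apply_exclusivity(status, traits)
  colnames(status) <- nm

  persons <- data.frame(person_id = pid, family_id = fam_of,
                        generation = generation, sex = sex,
                        birth_year = birth, father_id = father,
                        mother_id = mother,
                        age_at_death_or_emigration = cens_age,
                        stringsAsFactors = FALSE)

  ## --- diagnosis events -------------------------------------------------
  dx <- vector("list", tn)
  onset <- config$onset_range
  for (t in seq_len(tn)) {
    aff <- which(status[, t] == 1L)
    if (!length(aff)) next
    codes <- traits[[t]]$codes
    if (identical(codes, nm[t]) && nm[t] %in% names(.default_trait_codes))
      codes <- .default_trait_codes[[nm[t]]]
    dx[[t]] <- data.frame(person_id = aff,
                          code = sample(codes, length(aff), replace = TRUE),
                          age = round(stats::runif(length(aff), onset[1L],
                                                   onset[2L]), 1),
                          stringsAsFactors = FALSE)
  }
  diagnoses <- do.call(rbind, dx[!vapply(dx, is.null, logical(1))])
  if (is.null(diagnoses))
    diagnoses <- data.frame(person_id = integer(), code = character(),
                            age = numeric())

  ## comorbid conversion diagnoses around the first MDD code
  comorbid_codes <- list(scz_sad = c("F20", "F25"),
                         bd = c("F31.0", "F31.1", "F31.2"),
                         other_psych = c("F22", "F23", "F28", "F29"))
  conv_rows <- list()
  for (subtype in intersect(names(config$conversion), nm)) {
    cases <- which(status[, subtype] == 1L)
    if (!length(cases)) next
    first_age <- diagnoses$age[match(cases, diagnoses$person_id)]
    pars <- config$conversion[[subtype]]
    for (grp in names(comorbid_codes)) {
      p <- pars[[grp]] %||% 0
      hit <- cases[stats::runif(length(cases)) < p]
      if (!length(hit)) next
      before <- stats::runif(length(hit)) < (pars$p_before %||% 0.3)
      base_age <- first_age[match(hit, cases)]
      shift <- stats::runif(length(hit), 0.5, 5)
      age <- ifelse(before, pmax(10, base_age - shift), base_age + shift)
      conv_rows[[paste(subtype, grp)]] <- data.frame(
        person_id = hit,
        code = sample(comorbid_codes[[grp]], length(hit), replace = TRUE),
        age = round(age, 1), stringsAsFactors = FALSE)
    }
  }
  diagnoses <- rbind(diagnoses, do.call(rbind, conv_rows))
  rownames(diagnoses) <- NULL

  ## --- treatment events -------------------------------------------------
  tr_rows <- list()
  for (subtype in intersect(names(config$treatment), nm)) {
    cases <- which(status[, subtype] == 1L)
    if (!length(cases)) next
    first_age <- diagnoses$age[match(cases, diagnoses$person_id)]
    pars <- config$treatment[[subtype]]
    ap <- cases[stats::runif(length(cases)) < (pars$antipsychotic %||% 0)]
    ect <- cases[stats::runif(length(cases)) < (pars$ect %||% 0)]
    if (length(ap))
      tr_rows[[paste(subtype, "ap")]] <- data.frame(
        person_id = ap, code = "N05A",
        age = round(first_age[match(ap, cases)] +
                      stats::runif(length(ap), 0, 2), 1))
    if (length(ect))
      tr_rows[[paste(subtype, "ect")]] <- data.frame(
        person_id = ect, code = "9218",
        age = round(first_age[match(ect, cases)] +
                      stats::runif(length(ect), 0, 2), 1))
  }
  treatments <- do.call(rbind, tr_rows)
  if (is.null(treatments))
    treatments <- data.frame(person_id = integer(), code = character(),
                             age = numeric())
  rownames(treatments) <- NULL

  ## --- polygenic scores -------------------------------------------------
  prs <- NULL
  if (!is.null(config$prs_specs)) {
    ns <- length(config$prs_specs)
    R <- matrix(config$prs_cor, ns, ns); diag(R) <- 1
    X <- matrix(stats::rnorm(total * ns), total, ns) %*% chol(R)
    psych <- if ("psychotic_mdd" %in% nm) status[, "psychotic_mdd"] else 0L
    X <- X + outer(psych, unname(config$prs_specs))
    colnames(X) <- names(config$prs_specs)
    prs <- data.frame(person_id = pid, X, check.names = FALSE)
  }

  truth <- list(traits = lapply(traits, unclass), rg = config$rg,
                rc = config$rc, re = config$re,
                kappa_half = config$kappa_half,
                conversion = config$conversion,
                treatment = config$treatment,
                prs_specs = as.list(config$prs_specs),
                seed = config$seed)

  list(persons = persons, diagnoses = diagnoses, treatments = treatments,
       prs = prs, status = status, truth = truth)
}

#' Simulate proband-relative pairs with a prescribed aggregation odds ratio
#'
#' Pair-level generator for calibrating the familial-aggregation estimator:
#' the proband's affection is Bernoulli at the baseline prevalence and the
#' relative's conditional odds are multiplied by `or` when the proband is
#' affected. Because the odds ratio of a 2x2 table is direction-symmetric,
#' the both-orderings GEE dataset built from these pairs has the same
#' generating OR.
#'
#' @param n_pairs number of pairs (one family each).
#' @param prevalence baseline affection probability.
#' @param or generating odds ratio (> 0).
#' @param birth_year_range range for the relatives' birth years.
#' @return data frame with one row per pair: `family_id`, affection of both
#'   members, and sex/birth-year covariates for each member.
#' @export
simulate_aggregation_pairs <- function(n_pairs, prevalence, or,
                                       birth_year_range = c(1958L, 1993L)) {
  stopifnot(n_pairs >= 1, prevalence > 0, prevalence < 1, or > 0)
  y_a <- stats::rbinom(n_pairs, 1L, prevalence)
  logit0 <- stats::qlogis(prevalence)
  y_b <- stats::rbinom(n_pairs, 1L, stats::plogis(logit0 + log(or) * y_a))
  data.frame(family_id = seq_len(n_pairs), y_a = y_a, y_b = y_b,
             sex_a = sample(c("F", "M"), n_pairs, replace = TRUE),
             sex_b = sample(c("F", "M"), n_pairs, replace = TRUE),
             birth_year_a = sample(seq(birth_year_range[1L],
                                       birth_year_range[2L]),
                                   n_pairs, replace = TRUE),
             birth_year_b = sample(seq(birth_year_range[1L],
                                       birth_year_range[2L]),
                                   n_pairs, replace = TRUE))
}

#' Simulate a genotyped case-case cohort of MDD cases
#'
#' Generates MDD cases with standardized polygenic-score columns and a
#' psychotic / non-psychotic label drawn from a logistic model on the scores
#' plus sex and age covariates, for calibrating the case-case association
#' estimators.
#'
#' @param n_cases number of MDD cases (>= 2).
#' @param log_or named numeric vector of generating per-SD log odds ratios,
#'   one per score.
#' @param score_cor common pairwise correlation between score columns.
#' @param p_psychotic target marginal fraction of psychotic cases; the
#'   intercept is calibrated against the realised covariate draws.
#' @param beta_sex,beta_age generating log-ORs for the sex indicator and the
#'   standardized age covariate.
#' @param max_retry draws regenerated (with a warning) if one class is empty.
#' @return data frame with `psychotic` (0/1), score columns, `sex`, `age`.
#' @export
simulate_prs_casecase <- function(n_cases, log_or, score_cor = 0.3,
                                  p_psychotic = 0.05, beta_sex = 0.1,
                                  beta_age = 0.05, max_retry = 5L) {
  stopifnot(n_cases >= 2, length(log_or) >= 1)
  ns <- length(log_or)
  nm <- names(log_or) %||% paste0("score", seq_len(ns))
  R <- matrix(score_cor, ns, ns); diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("score correlation matrix is not PSD")
  for (attempt in seq_len(max_retry)) {
    X <- matrix(stats::rnorm(n_cases * ns), n_cases, ns) %*%
      chol(R + diag(1e-12, ns))
    X <- scale(X)  # standardized within the sample
    sexM <- stats::rbinom(n_cases, 1L, 0.4)
    age <- round(stats::rnorm(n_cases, 50, 10), 1)
    lp <- drop(X %*% unname(log_or)) + beta_sex * sexM +
      beta_age * as.numeric(scale(age))
    alpha <- stats::uniroot(function(a) mean(stats::plogis(a + lp)) -
                              p_psychotic,
                            c(-30, 30), tol = 1e-10)$root
    y <- stats::rbinom(n_cases, 1L, stats::plogis(alpha + lp))
    if (length(unique(y)) == 2L) {
      out <- data.frame(psychotic = y, X, check.names = FALSE)
      names(out)[1L + seq_len(ns)] <- nm
      out$sex <- ifelse(sexM == 1L, "M", "F")
      out$age <- age
      return(out)
    }
    warning("degenerate draw (single class); regenerating")
  }
  stop("failed to generate both classes after ", max_retry, " attempts")
}

#' Write the synthetic register to TSV files
#'
#' Writes `persons.tsv`, `diagnoses.tsv`, `treatments.tsv`, optionally
#' `prs.tsv`, and echoes the generating parameters to `truth.json`.
#'
#' @param pop result of [simulate_population()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_registry <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(pop$persons, "persons.tsv")
  wr(pop$diagnoses, "diagnoses.tsv")
  wr(pop$treatments, "treatments.tsv")
  if (!is.null(pop$prs)) wr(pop$prs, "prs.tsv")
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(pop$truth, tp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, tp))
}
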
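## Cohort construction: ICD-10 phenotype definitions, eligibility filtering,
## relative-pair extraction and descriptive summaries.

#' Default ICD-10 code sets
#'
#' Returns the code sets used to classify MDD and comorbid disorders.
#' `psychotic_mdd` follows the register convention F32.3/F33.3 (psychotic
#' depressive episodes); an alternative set `psychotic_mdd_severe_incl`
#' (F32.2/F32.3) is shipped because both conventions exist for severe
#' episode sub-codes, selectable via configuration rather than silently.
#' `other_psychotic` is F2x excluding F20 and F25.
#'
#' @param path optional YAML file overriding the shipped defaults
#'   (see `inst/extdata/codes.yaml` for the format).
#' @return named list of character vectors of dot-normalised uppercase
#'   ICD-10 code prefixes.
#' @export
default_codesets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "codes.yaml", package = "famliab")
  cs <- yaml::read_yaml(path)
  lapply(cs, function(x) normalize_icd(unlist(x)))
}

#' Normalise ICD-10 code strings
#'
#' Uppercases and dot-normalises codes ("f323" -> "F32.3"); errors on
#' strings that do not look like ICD-10 codes.
#'
#' @param codes character vector.
#' @return normalised character vector.
#' @export
normalize_icd <- function(codes) {
  x <- toupper(gsub("[[:space:]]", "", codes))
  x <- ifelse(grepl("^[A-Z][0-9]{3,}$", x),
              sub("^([A-Z][0-9]{2})", "\\1.", x), x)
  bad <- !grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$|^[0-9A-Z]{4,6}$", x)
  if (any(bad))
    stop("codes not recognisable as ICD-10: ",
         paste(unique(codes[bad]), collapse = ", "))
  x
}

## prefix match: diagnosis code belongs to set if it equals or extends a
## set prefix ("F32.3" matches prefix "F32"; "F32" does not match "F32.3")
code_in_set <- function(codes, set) {
  if (!length(set)) return(rep(FALSE, length(codes)))
  pat <- paste0("^(", paste0(gsub("\\.", "\\\\.", set), collapse = "|"),
                ")")
  grepl(pat, codes)
}

#' Classify persons into MDD subtypes from diagnosis events
#'
#' Implements the register phenotype: any psychotic-MDD code makes the
#' person `psychotic_mdd`; other MDD codes only make them
#' `non_psychotic_mdd`; otherwise `none`. Under the `restrictive`
#' definition, persons with any bipolar code are removed from all MDD, and
#' persons with schizophrenia/schizoaffective codes are additionally removed
#' from psychotic MDD (labelled `none`, not demoted).
#'
#' @param persons persons data frame (needs `person_id`).
#' @param diagnoses diagnosis events (`person_id`, `code`).
#' @param codesets named list as from [default_codesets()]; needs entries
#'   `psychotic_mdd`, `mdd`, and for the restrictive definition `bd` and
#'   `scz_sad`.
#' @param definition `"main"` or `"restrictive"`.
#' @return data frame `person_id`, `label` (factor none /
#'   non_psychotic_mdd / psychotic_mdd); labels are mutually exclusive and
#'   exhaustive.
#' @export
classify_mdd <- function(persons, diagnoses, codesets = default_codesets(),
                         definition = c("main", "restrictive")) {
  definition <- match.arg(definition)
  codes <- normalize_icd(diagnoses$code)
  pid <- diagnoses$person_id
  has <- function(set) unique(pid[code_in_set(codes, set)])
  psych <- has(codesets$psychotic_mdd)
  mdd_any <- union(has(codesets$mdd), psych)
  if (definition == "restrictive") {
    bd <- has(codesets$bd)
    scz <- has(codesets$scz_sad)
    mdd_any <- setdiff(mdd_any, bd)
    psych <- setdiff(setdiff(psych, bd), scz)
    ## psychotic cases dropped for SCZ/SAD leave the MDD pool entirely
    mdd_any <- setdiff(mdd_any, setdiff(has(codesets$psychotic_mdd), psych))
  }
  label <- rep("none", nrow(persons))
  label[persons$person_id %in% mdd_any] <- "non_psychotic_mdd"
  label[persons$person_id %in% psych] <- "psychotic_mdd"
  data.frame(person_id = persons$person_id,
             label = factor(label, levels = c("none", "non_psychotic_mdd",
                                              "psychotic_mdd")))
}

#' Apply register eligibility filters
#'
#' Keeps persons born inside the study birth window and not censored (dead
#' or emigrated) before the minimum follow-up age.
#'
#' @param persons persons data frame.
#' @param birth_window inclusive birth-year range, or `NULL` to skip.
#' @param min_followup_age censoring cut-off in years (default 20).
#' @return filtered persons data frame, with attribute `n_removed`.
#' @export
apply_eligibility <- function(persons, birth_window = NULL,
                              min_followup_age = 20) {
  keep <- rep(TRUE, nrow(persons))
  if (!is.null(birth_window))
    keep <- keep & persons$birth_year >= birth_window[1L] &
      persons$birth_year <= birth_window[2L]
  cens <- persons$age_at_death_or_emigration
  keep <- keep & (is.na(cens) | cens >= min_followup_age)
  out <- persons[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Extract relative pairs from pedigree links
#'
#' Full siblings share both parents; half siblings exactly one; first
#' cousins have parents who are full siblings. Each unordered pair is
#' returned once. The birth-gap filter (default 10 years) applies to full-
#' and half-sibling pairs only.
#'
#' @param persons persons data frame with `person_id`, `family_id`,
#'   `father_id`, `mother_id`, `birth_year`.
#' @param max_birth_gap maximum absolute birth-year difference for sibling
#'   pairs; `Inf` disables the filter.
#' @param kappa_half shared-environment sharing recorded for half-sib pairs.
#' @return data frame with `person_a`, `person_b`, `kinship`, `a_share`,
#'   `c_share`, `family_id`.
#' @export
extract_pairs <- function(persons, max_birth_gap = 10, kappa_half = 0) {
  pid <- persons$person_id
  if (anyDuplicated(pid)) stop("duplicate person ids")
  ## guard against pedigree cycles: a person may not be its own ancestor
  check_cycles(persons)
  idx <- seq_along(pid)
  fa <- match(persons$father_id, pid)
  mo <- match(persons$mother_id, pid)
  fam <- persons$family_id
  by <- persons$birth_year

  pair_rows <- function(i, j, kinship, a_share, c_share) {
    if (!length(i)) return(NULL)
    swap <- pid[i] > pid[j]
    a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
    data.frame(person_a = pid[a], person_b = pid[b], kinship = kinship,
               a_share = a_share, c_share = c_share, family_id = fam[a],
               stringsAsFactors = FALSE)
  }

  ## --- full sibs: same (father, mother), both known ---------------------
  ## the birth-gap filter applies to the analysed sibling pairs, not to the
  ## pedigree itself, so cousinship below is derived from the unfiltered set
  sib_key <- ifelse(!is.na(fa) & !is.na(mo), paste(fa, mo), NA)
  fs_raw <- pairs_within_groups(idx, sib_key)
  keep <- abs(by[fs_raw$i] - by[fs_raw$j]) <= max_birth_gap
  fs <- fs_raw[keep, , drop = FALSE]

  ## --- half sibs: share exactly one parent ------------------------------
  hs_i <- integer(0); hs_j <- integer(0)
  for (par in list(fa, mo)) {
    key <- ifelse(!is.na(par), as.character(par), NA)
    pp <- pairs_within_groups(idx, key)
    same_both <- !is.na(fa[pp$i]) & !is.na(fa[pp$j]) &
      !is.na(mo[pp$i]) & !is.na(mo[pp$j]) &
      fa[pp$i] == fa[pp$j] & mo[pp$i] == mo[pp$j]
    hs_i <- c(hs_i, pp$i[!same_both]); hs_j <- c(hs_j, pp$j[!same_both])
  }
  if (length(hs_i)) {
    o <- !duplicated(paste(pmin(hs_i, hs_j), pmax(hs_i, hs_j)))
    hs_i <- hs_i[o]; hs_j <- hs_j[o]
    keep <- abs(by[hs_i] - by[hs_j]) <= max_birth_gap
    hs_i <- hs_i[keep]; hs_j <- hs_j[keep]
  }

  ## --- cousins: a parent of A and a parent of B are full sibs -----------
  fs_all <- fs_raw  # full-sib index pairs (any generation), unfiltered
  cz_i <- integer(0); cz_j <- integer(0)
  if (nrow(fs_all)) {
    par_vec <- c(fa, mo)
    child_vec <- c(idx, idx)
    ok <- !is.na(par_vec)
    kids_of <- split(child_vec[ok], factor(par_vec[ok], levels = idx))
    for (r in seq_len(nrow(fs_all))) {
      u <- fs_all$i[r]; v <- fs_all$j[r]
      ku <- kids_of[[u]]; kv <- kids_of[[v]]
      if (!length(ku) || !length(kv)) next
      grid <- expand.grid(i = ku, j = kv)
      ## exclude pairs that are themselves sibs (shared other parent)
      sib <- (!is.na(fa[grid$i]) & !is.na(fa[grid$j]) &
                fa[grid$i] == fa[grid$j]) |
        (!is.na(mo[grid$i]) & !is.na(mo[grid$j]) & mo[grid$i] == mo[grid$j])
      cz_i <- c(cz_i, grid$i[!sib]); cz_j <- c(cz_j, grid$j[!sib])
    }
    if (length(cz_i)) {
      o <- !duplicated(paste(pmin(cz_i, cz_j), pmax(cz_i, cz_j)))
      cz_i <- cz_i[o]; cz_j <- cz_j[o]
    }
  }

  out <- rbind(pair_rows(fs$i, fs$j, "full_sib", 0.5, 1),
               pair_rows(hs_i, hs_j, "half_sib", 0.25, kappa_half),
               pair_rows(cz_i, cz_j, "cousin", 0.125, 0))
  if (is.null(out))
    out <- data.frame(person_a = integer(), person_b = integer(),
                      kinship = character(), a_share = numeric(),
                      c_share = numeric(), family_id = integer())
  rownames(out) <- NULL
  out
}

## all unordered index pairs sharing a non-NA key, as data.frame(i, j)
pairs_within_groups <- function(idx, key) {
  grp <- split(idx[!is.na(key)], key[!is.na(key)])
  grp <- grp[lengths(grp) >= 2L]
  if (!length(grp)) return(data.frame(i = integer(), j = integer()))
  res <- lapply(grp, function(g) {
    cb <- utils::combn(g, 2L)
    data.frame(i = cb[1L, ], j = cb[2L, ])
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

check_cycles <- function(persons) {
  pid <- persons$person_id
  fa <- match(persons$father_id, pid)
  mo <- match(persons$mother_id, pid)
  n <- length(pid)
  ## iterative ancestor walk; depth can never exceed n in an acyclic pedigree
  cur <- unique(c(fa[!is.na(fa)], mo[!is.na(mo)]))
  start <- seq_len(n)
  anc <- cbind(fa, mo)
  for (i in start) {
    seen <- logical(n)
    frontier <- i
    repeat {
      frontier <- unique(c(anc[frontier, 1L], anc[frontier, 2L]))
      frontier <- frontier[!is.na(frontier)]
      if (!length(frontier)) break
      if (any(frontier == i)) stop("pedigree cycle involving person ",
                                   pid[i])
      new <- frontier[!seen[frontier]]
      if (!length(new)) break
      seen[new] <- TRUE
      frontier <- new
    }
  }
  invisible(TRUE)
}

#' Diagnostic-conversion table around the first MDD diagnosis
#'
#' For each MDD subtype, the (non-mutually-exclusive) proportions of cases
#' with bipolar disorder, schizophrenia/schizoaffective disorder, and other
#' psychotic disorders before versus after their first MDD diagnosis. A
#' comorbid code dated exactly at the first MDD code counts as "before"
#' (conversion-to-MDD reading; set `tie` to change).
#'
#' @param labels output of [classify_mdd()].
#' @param diagnoses diagnosis events with `person_id`, `code`, `age`.
#' @param codesets code sets; uses `mdd`, `psychotic_mdd`, `bd`, `scz_sad`,
#'   `other_psychotic`.
#' @param tie `"before"` or `"after"` for exact age ties.
#' @return data frame with one row per subtype x disorder group x timing and
#'   the proportion among that subtype's cases; attribute `n_missing_age`
#'   counts events dropped for missing ages.
#' @export
conversion_table <- function(labels, diagnoses,
                             codesets = default_codesets(),
                             tie = c("before", "after")) {
  tie <- match.arg(tie)
  codes <- normalize_icd(diagnoses$code)
  miss <- is.na(diagnoses$age)
  if (any(miss)) {
    warning(sum(miss), " diagnosis events with missing age excluded")
    diagnoses <- diagnoses[!miss, , drop = FALSE]
    codes <- codes[!miss]
  }
  mdd_set <- unique(c(codesets$mdd, codesets$psychotic_mdd))
  is_mdd <- code_in_set(codes, mdd_set)
  first_mdd <- tapply(diagnoses$age[is_mdd], diagnoses$person_id[is_mdd],
                      min)
  groups <- c(bd = "bd", scz_sad = "scz_sad",
              other_psychotic = "other_psychotic")
  subtypes <- c("psychotic_mdd", "non_psychotic_mdd")
  rows <- list()
  for (st in subtypes) {
    ids <- labels$person_id[labels$label == st]
    n <- length(ids)
    fm <- first_mdd[as.character(ids)]
    for (g in groups) {
      in_g <- code_in_set(codes, codesets[[g]]) &
        diagnoses$person_id %in% ids
      gage <- tapply(diagnoses$age[in_g], diagnoses$person_id[in_g], min)
      m <- match(names(gage), as.character(ids))
      ref <- fm[m]
      before <- if (tie == "before") gage <= ref else gage < ref
      rows[[paste(st, g)]] <- data.frame(
        subtype = st, disorder = g,
        p_before = if (n) sum(before, na.rm = TRUE) / n else NA_real_,
        p_after = if (n) sum(!before, na.rm = TRUE) / n else NA_real_,
        p_any = if (n) length(gage) / n else NA_real_,
        n_cases = n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_missing_age") <- sum(miss)
  out
}

#' Cohort descriptive summary
#'
#' Counts and percentages in the style of a register sample-characteristics
#' table: total persons, % female, MDD cases, psychotic MDD cases, the share
#' of psychotic MDD among all MDD, and its population prevalence.
#'
#' @param persons persons data frame (needs `sex`).
#' @param labels output of [classify_mdd()].
#' @return one-row data frame.
#' @export
descriptives <- function(persons, labels) {
  n <- nrow(persons)
  lab <- labels$label[match(persons$person_id, labels$person_id)]
  n_mdd <- sum(lab != "none", na.rm = TRUE)
  n_psych <- sum(lab == "psychotic_mdd", na.rm = TRUE)
  data.frame(
    n_total = n,
    n_female = sum(persons$sex == "F"),
    pct_female = if (n) 100 * sum(persons$sex == "F") / n else NA_real_,
    n_mdd = n_mdd,
    pct_mdd = if (n) 100 * n_mdd / n else NA_real_,
    n_psychotic_mdd = n_psych,
    pct_psychotic_in_mdd = if (n_mdd) 100 * n_psych / n_mdd else NA_real_,
    pct_psychotic_in_pop = if (n) 100 * n_psych / n else NA_real_)
}
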
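## End-to-end orchestration: generate -> phenotype -> pairs -> familial
## aggregation -> liability models -> PRS -> meta-analysis, with every
## artifact written as TSV/JSON and checksummed in a manifest.

#' Run the full synthetic-register analysis pipeline
#'
#' Executes every stage on one or more generated cohorts ("countries"):
#' register simulation, phenotype classification, eligibility filtering,
#' relative-pair extraction, descriptive and conversion tables, familial
#' aggregation odds ratios per kinship class, AE/ACE liability fits with
#' family-bootstrap confidence intervals, genetic correlation between the
#' exclusive MDD subtypes when both are simulated, case-case PRS models
#' when scores are simulated, and a fixed-effect meta-analysis across
#' cohorts. Deterministic given the configuration seeds.
#'
#' @param configs a [registry_config()] or list of them (one per cohort).
#' @param out_dir output directory.
#' @param definition phenotype definition passed to [classify_mdd()].
#' @param n_boot bootstrap replicates for the liability fits.
#' @param kinships kinship classes analysed for familial aggregation.
#' @return (invisibly) a list with the per-cohort results, the meta
#'   estimates, and the manifest path.
#' @export
run_pipeline <- function(configs, out_dir, definition = "main",
                         n_boot = 200L,
                         kinships = c("full_sib", "half_sib", "cousin")) {
  if (inherits(configs, "registry_config")) configs <- list(configs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  codesets <- default_codesets()
  cohort_results <- list()

  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    cdir <- file.path(out_dir, sprintf("cohort%d", ci))
    logf("[cohort %d] simulating register (seed %d)", ci, cfg$seed)
    pop <- simulate_population(cfg)
    write_registry(pop, cdir)

    labels <- classify_mdd(pop$persons, pop$diagnoses, codesets,
                           definition = definition)
    study <- pop$persons[pop$persons$generation == 2L, , drop = FALSE]
    eligible <- apply_eligibility(study, cfg$birth_year_range)
    logf("[cohort %d] eligibility: %d of %d study persons retained (%d removed)",
         ci, nrow(eligible), nrow(study), attr(eligible, "n_removed"))
    ## pedigree links are resolved on the full register (parents live
    ## outside the study birth window); analysed pairs are then restricted
    ## to eligible study persons
    pairs <- extract_pairs(pop$persons, max_birth_gap = 10,
                           kappa_half = cfg$kappa_half)
    pairs <- pairs[pairs$person_a %in% eligible$person_id &
                     pairs$person_b %in% eligible$person_id, , drop = FALSE]
    logf("[cohort %d] pairs: %s", ci,
         paste(names(table(pairs$kinship)), table(pairs$kinship),
               sep = "=", collapse = ", "))

    desc <- descriptives(eligible, labels)
    conv <- conversion_table(labels, pop$diagnoses, codesets)
    utils::write.table(labels, file.path(cdir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(pairs, file.path(cdir, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(desc, file.path(cdir, "descriptives.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(conv, file.path(cdir, "conversion.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    ## --- familial aggregation ------------------------------------------
    expo <- data.frame(person_id = labels$person_id,
                       exposed = as.integer(labels$label ==
                                              "psychotic_mdd"))
    agg <- list()
    for (k in intersect(kinships, unique(pairs$kinship))) {
      pk <- pairs[pairs$kinship == k, , drop = FALSE]
      dk <- pair_dataset(pk, expo, persons = pop$persons)
      est <- tryCatch(fit_cluster_logit(dk, label = paste0("agg_", k)),
                      error = function(e) {
                        logf("[cohort %d] aggregation %s skipped: %s", ci,
                             k, conditionMessage(e)); NULL
                      })
      if (!is.null(est)) agg[[k]] <- est
    }
    agg_df <- if (length(agg)) bonferroni(agg) else NULL
    if (!is.null(agg_df))
      utils::write.table(agg_df, file.path(cdir, "famrisk.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

    ## --- liability models ----------------------------------------------
    aff <- data.frame(person_id = labels$person_id,
                      affected = as.integer(labels$label ==
                                              "psychotic_mdd"))
    liab <- liability_stage(pairs, labels, n_boot = n_boot,
                            seed = cfg$seed + 7L)
    jsonlite::write_json(liability_report(liab),
                         file.path(cdir, "liability.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    ## --- PRS case-case --------------------------------------------------
    prs_res <- NULL
    if (!is.null(pop$prs)) {
      cases <- labels$person_id[labels$label != "none"]
      pd <- pop$prs[pop$prs$person_id %in% cases, , drop = FALSE]
      pd$psychotic <- as.integer(
        labels$label[match(pd$person_id, labels$person_id)] ==
          "psychotic_mdd")
      m <- match(pd$person_id, pop$persons$person_id)
      pd$sex <- pop$persons$sex[m]
      pd$age <- cfg$followup_end - pop$persons$birth_year[m]
      sc <- setdiff(names(pop$prs), "person_id")
      prs_res <- tryCatch(
        list(univariate = fit_prs_models(pd, sc, mode = "univariate"),
             joint = fit_prs_models(pd, setdiff(sc, "bd"), mode = "joint")),
        error = function(e) {
          logf("[cohort %d] PRS stage skipped: %s", ci,
               conditionMessage(e)); NULL
        })
      if (!is.null(prs_res)) {
        prs_df <- do.call(rbind, lapply(
          c(prs_res$univariate, prs_res$joint), as.data.frame))
        prs_df$mode <- c(rep("univariate", length(prs_res$univariate)),
                         rep("joint", length(prs_res$joint)))
        utils::write.table(prs_df, file.path(cdir, "prs_assoc.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    cohort_results[[ci]] <- list(descriptives = desc, conversion = conv,
                                 aggregation = agg, liability = liab,
                                 prs = prs_res, dir = cdir)
  }

  ## --- meta-analysis across cohorts -------------------------------------
  meta <- list()
  for (k in kinships) {
    ests <- Filter(Negate(is.null),
                   lapply(cohort_results, function(cr) cr$aggregation[[k]]))
    if (length(ests))
      meta[[paste0("agg_", k)]] <- meta_fixed(ests,
                                              label = paste0("agg_", k))
  }
  h2s <- lapply(cohort_results, function(cr) cr$liability$h2_ae)
  h2s <- Filter(Negate(is.null), h2s)
  if (length(h2s)) {
    ## raw-scale inverse-variance pooling with bootstrap SEs
    est <- vapply(h2s, function(x) x$a2, numeric(1))
    se <- vapply(h2s, function(x) x$boot_se %||% NA_real_, numeric(1))
    if (all(is.finite(se)) && all(se > 0)) {
      w <- 1 / se^2
      meta$h2 <- list(estimate = sum(w * est) / sum(w),
                      se = sqrt(1 / sum(w)))
    } else meta$h2 <- list(estimate = mean(est), se = NA_real_)
  }
  if (length(meta)) {
    meta_df <- do.call(rbind, lapply(names(meta), function(nmm) {
      m <- meta[[nmm]]
      if (inherits(m, "assoc_estimate")) {
        d <- as.data.frame(m); d$label <- nmm; d[c("label", "or", "ci_low",
                                                   "ci_high", "p_value")]
      } else data.frame(label = nmm, or = NA, ci_low = NA, ci_high = NA,
                        p_value = NA)
    }))
    utils::write.table(meta_df, file.path(out_dir, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## --- manifest ----------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  files <- files[!grepl("\\.log$", files)]  # log lines carry wall-clock times
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("pipeline complete: %d files in manifest", nrow(manifest))
  invisible(list(cohorts = cohort_results, meta = meta,
                 manifest = file.path(out_dir, "manifest.json")))
}

## liability stage: univariate h2 for psychotic MDD (AE + ACE + C=0 test)
## and, when both MDD subtypes are present, the exclusive-trait rg
liability_stage <- function(pairs, labels, n_boot = 200L, seed = 1L) {
  lab <- labels$label
  cat_of <- function(ids) {
    l <- lab[match(ids, labels$person_id)]
    ifelse(l == "psychotic_mdd", 1L, ifelse(l == "non_psychotic_mdd", 2L,
                                            0L))
  }
  out <- list()
  kin_used <- c("full_sib", "cousin")
  pk <- pairs[pairs$kinship %in% kin_used, , drop = FALSE]
  if (!all(kin_used %in% pk$kinship)) return(out)
  ca <- cat_of(pk$person_a)
  cb <- cat_of(pk$person_b)
  kin <- pk$kinship

  tab2 <- function(w, which_cat) {
    lapply(stats::setNames(kin_used, kin_used), function(k) {
      s <- kin == k
      pair_crosstable((ca[s] == which_cat) + 0L, (cb[s] == which_cat) + 0L,
                      2L, weights = w[s])
    })
  }
  w1 <- rep(1, nrow(pk))
  ae <- tryCatch(fit_ace_wls(tab2(w1, 1L), "AE"), error = function(e) NULL)
  if (is.null(ae)) return(out)
  ace <- fit_ace_wls(tab2(w1, 1L), "ACE")
  out$h2_ae <- ae
  out$h2_ace <- ace
  out$c_test <- compare_models(ace, ae, df = 1L, boundary = ace$c2 <= 0)

  bt <- tryCatch(
    bootstrap_ci(function(w) {
      f <- tryCatch(fit_ace_wls(tab2(w, 1L), "AE"),
                    error = function(e) NULL)
      c(a2 = if (is.null(f)) NA_real_ else f$a2)
    }, pk$family_id, n_boot = n_boot, seed = seed),
    error = function(e) NULL)
  if (!is.null(bt)) {
    out$h2_ae$boot_ci <- bt$ci
    out$h2_ae$boot_se <- stats::sd(bt$replicates[, "a2"], na.rm = TRUE)
    out$h2_ae$n_boot <- n_boot
  }

  if (any(ca == 2L) || any(cb == 2L)) {
    tab3 <- lapply(stats::setNames(kin_used, kin_used), function(k) {
      s <- kin == k
      pair_crosstable(ca[s], cb[s], 3L)
    })
    ae2 <- tryCatch(fit_ace_wls(tab2(w1, 2L), "AE"),
                    error = function(e) NULL)
    if (!is.null(ae2)) {
      out$h2_ae_nonpsych <- ae2
      out$rg_exclusive <- tryCatch(
        fit_rg_ml(tab3, a2 = c(ae$a2, ae2$a2), exclusive = TRUE),
        error = function(e) NULL)
    }
  }
  out
}

liability_report <- function(liab) {
  rep1 <- function(f) {
    if (is.null(f)) return(NULL)
    list(model = f$model, estimator = f$estimator, a2 = f$a2, c2 = f$c2,
         e2 = f$e2, rg = f$rg, fit_statistic = f$fit_statistic,
         logLik = f$logLik,
         boot_ci = if (!is.null(f$boot_ci))
           as.list(as.data.frame(t(f$boot_ci))) else NULL)
  }
  list(h2_ae = rep1(liab$h2_ae), h2_ace = rep1(liab$h2_ace),
       c_test = liab$c_test,
       h2_ae_nonpsych = rep1(liab$h2_ae_nonpsych),
       rg_exclusive = rep1(liab$rg_exclusive))
}
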
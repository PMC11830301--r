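## Familial aggregation / coaggregation: logistic models with
## family-clustered sandwich standard errors. Point estimates are ordinary
## logistic maximum likelihood, identical to generalised estimating
## equations with an independence working correlation; the cluster sandwich
## (no small-sample adjustment) supplies the robust SEs.

#' Construct an association estimate
#'
#' Container for a log odds ratio with robust standard error, the shared
#' currency of the familial-aggregation, polygenic-score and meta-analysis
#' stages. The 95% CI is normal-theory on the log scale and the p-value a
#' two-sided Wald test.
#'
#' @param label estimate label.
#' @param log_or log odds ratio.
#' @param robust_se standard error of `log_or`.
#' @param n_pairs,n_clusters bookkeeping counts (may be `NA`).
#' @return object of class `assoc_estimate`.
#' @export
assoc_estimate <- function(label, log_or, robust_se, n_pairs = NA_integer_,
                           n_clusters = NA_integer_) {
  z <- log_or / robust_se
  structure(list(label = label, log_or = log_or, robust_se = robust_se,
                 or = exp(log_or),
                 ci_low = exp(log_or - 1.96 * robust_se),
                 ci_high = exp(log_or + 1.96 * robust_se),
                 p_value = 2 * stats::pnorm(-abs(z)),
                 n_pairs = n_pairs, n_clusters = n_clusters),
            class = "assoc_estimate")
}

#' @export
print.assoc_estimate <- function(x, ...) {
  cat(sprintf("%s: OR = %.3f (95%% CI %.3f-%.3f), p = %.3g", x$label,
              x$or, x$ci_low, x$ci_high, x$p_value))
  if (!is.na(x$n_pairs)) cat(sprintf("  [n_pairs = %d", x$n_pairs))
  if (!is.na(x$n_clusters)) cat(sprintf(", clusters = %d]", x$n_clusters))
  else if (!is.na(x$n_pairs)) cat("]")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.assoc_estimate <- function(x, ...) {
  data.frame(label = x$label, log_or = x$log_or, robust_se = x$robust_se,
             or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
             p_value = x$p_value, n_pairs = x$n_pairs,
             n_clusters = x$n_clusters)
}

#' Build the long-format proband-relative dataset
#'
#' Each unordered relative pair contributes both orderings: each member
#' appears once as the proband (supplying the exposure) and once as the
#' relative (supplying the outcome and the covariates). The family id is
#' attached for sandwich clustering; the both-orderings expansion is why
#' clustering is required.
#'
#' @param pairs relative pairs (from [extract_pairs()] or equivalent) with
#'   `person_a`, `person_b`, `family_id`.
#' @param exposure data frame `person_id`, `exposed` (0/1): the proband
#'   phenotype.
#' @param outcome data frame `person_id`, `affected` (0/1): the relative
#'   phenotype; defaults to the exposure phenotype (aggregation).
#' @param persons optional persons table supplying relative `sex` and
#'   `birth_year` covariates.
#' @return data frame with one row per ordering: `outcome`, `exposure`,
#'   `family_id`, and relative covariates when available.
#' @export
pair_dataset <- function(pairs, exposure, outcome = exposure,
                         persons = NULL) {
  if (any(pairs$person_a == pairs$person_b))
    stop("self-pairing: person appears on both sides of a pair")
  if (!"affected" %in% names(outcome)) {
    # aggregation: the outcome phenotype is the exposure phenotype
    outcome$affected <- outcome$exposed
  }
  proband <- c(pairs$person_a, pairs$person_b)
  relative <- c(pairs$person_b, pairs$person_a)
  d <- data.frame(
    proband_id = proband, relative_id = relative,
    exposure = exposure$exposed[match(proband, exposure$person_id)],
    outcome = outcome$affected[match(relative, outcome$person_id)],
    family_id = c(pairs$family_id, pairs$family_id))
  if (!is.null(persons)) {
    m <- match(relative, persons$person_id)
    d$sex <- persons$sex[m]
    d$birth_year <- persons$birth_year[m]
  }
  d
}

#' Fit the cluster-robust logistic aggregation model
#'
#' Logistic regression of the relative's outcome on the proband's exposure
#' (plus covariates), with the sandwich variance clustered on family id and
#' no small-sample adjustment -- what GEE with an independence working
#' correlation reports for this design.
#'
#' @param data output of [pair_dataset()] (or any data frame with `outcome`,
#'   `exposure`, `family_id`).
#' @param covariates character vector of additional covariate columns
#'   (default: those of `sex`, `birth_year` that are present). Birth year is
#'   centred before entering linearly.
#' @param label estimate label.
#' @return an [assoc_estimate()] for the exposure coefficient.
#' @export
fit_cluster_logit <- function(data, covariates = NULL, label = "exposure") {
  if (length(unique(data$outcome)) < 2L)
    stop("outcome has a single class; cannot fit")
  if (is.null(covariates))
    covariates <- intersect(c("sex", "birth_year"), names(data))
  if ("birth_year" %in% covariates)
    data$birth_year <- data$birth_year - mean(data$birth_year, na.rm = TRUE)
  fml <- stats::reformulate(c("exposure", covariates), response = "outcome")
  ## tight convergence so closed-form 2x2 identities hold to ~1e-10
  fit <- stats::glm(fml, family = stats::binomial(), data = data,
                    control = stats::glm.control(epsilon = 1e-14,
                                                 maxit = 200L))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("singular design; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  if (any(abs(cf) > 15))
    stop("apparent separation (|coef| > 15 for ",
         paste(names(cf)[abs(cf) > 15], collapse = ", "),
         "); penalised estimation is out of scope")
  V <- sandwich::vcovCL(fit, cluster = data$family_id, type = "HC0",
                        cadjust = FALSE)
  est <- assoc_estimate(label, cf[["exposure"]],
                        sqrt(V["exposure", "exposure"]),
                        n_pairs = nrow(data) %/% 2L,
                        n_clusters = length(unique(data$family_id)))
  est$fit <- fit
  est
}

#' Bonferroni flagging of a set of association estimates
#'
#' @param results list of [assoc_estimate()] objects (or a data frame with a
#'   `p_value` column).
#' @param alpha family-wise error rate.
#' @return data frame of the estimates with the adjusted threshold
#'   (`alpha / n`) and a `significant` flag.
#' @export
bonferroni <- function(results, alpha = 0.05) {
  if (inherits(results, "assoc_estimate")) results <- list(results)
  df <- if (is.data.frame(results)) results
        else do.call(rbind, lapply(results, as.data.frame))
  thr <- alpha / nrow(df)
  df$bonferroni_threshold <- thr
  df$significant <- df$p_value < thr
  df
}
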
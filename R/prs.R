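## Case-case polygenic-score associations: standardized scores, univariate
## and joint logistic models for the psychotic vs non-psychotic contrast,
## and fixed-effect meta-analysis of association estimates.

#' Standardize polygenic-score columns
#'
#' Centres each score to mean 0 and scales to standard deviation 1 within
#' the analysis sample, using the sample (n - 1) standard deviation.
#' Idempotent; errors on zero-variance columns.
#'
#' @param scores data frame or matrix of numeric score columns.
#' @return object of the same shape with standardized columns.
#' @export
standardize <- function(scores) {
  num <- vapply(as.data.frame(scores), is.numeric, logical(1))
  out <- scores
  for (j in which(num)) {
    v <- scores[[j]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("zero-variance score column: ",
           colnames(scores)[j] %||% as.character(j))
    out[[j]] <- (v - mean(v)) / s
  }
  out
}

#' Case-case logistic models for polygenic scores
#'
#' Estimates the per-SD odds ratio of psychotic (vs non-psychotic) MDD for
#' each polygenic score, adjusted for the supplied covariates, either one
#' score at a time (`univariate`) or with all scores mutually adjusted in a
#' single model (`joint`). Scores are standardized within the analysis
#' sample before fitting. An aggregate bipolar score may not enter a joint
#' model together with its subtype scores (collinearity guard).
#'
#' @param data data frame with the outcome column, score columns and
#'   covariates.
#' @param scores character vector of score column names.
#' @param outcome name of the 0/1 outcome column (1 = psychotic).
#' @param covariates character vector of covariate column names; numeric
#'   covariates are centred.
#' @param mode `"univariate"` or `"joint"`.
#' @return list of [assoc_estimate()] objects, one per score.
#' @export
fit_prs_models <- function(data, scores, outcome = "psychotic",
                           covariates = intersect(c("sex", "age",
                                                    paste0("PC", 1:5)),
                                                  names(data)),
                           mode = c("univariate", "joint")) {
  mode <- match.arg(mode)
  stopifnot(all(scores %in% names(data)),
            all(covariates %in% names(data)))
  y <- data[[outcome]]
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  if (mode == "joint" && "bd" %in% tolower(scores) &&
      any(c("bd1", "bd_i", "bd2", "bd_ii") %in% tolower(scores)))
    stop("collinearity guard: aggregate BD score cannot enter a joint ",
         "model with BD subtype scores (",
         paste(scores, collapse = ", "), ")")
  data[scores] <- standardize(data[scores])
  for (cv in covariates)
    if (is.numeric(data[[cv]]))
      data[[cv]] <- data[[cv]] - mean(data[[cv]], na.rm = TRUE)

  fit_one <- function(terms) {
    fml <- stats::reformulate(c(terms, covariates), response = outcome)
    fit <- stats::glm(fml, family = stats::binomial(), data = data,
                      control = stats::glm.control(epsilon = 1e-14,
                                                   maxit = 200L))
    if (anyNA(stats::coef(fit)))
      stop("singular design; collinear columns: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    if (any(abs(stats::coef(fit)[terms]) > 15))
      stop("apparent separation in score coefficients")
    fit
  }

  if (mode == "joint") {
    fit <- fit_one(scores)
    se <- sqrt(diag(stats::vcov(fit)))
    out <- lapply(scores, function(s) {
      e <- assoc_estimate(s, stats::coef(fit)[[s]], se[[s]],
                          n_pairs = nrow(data))
      e$mode <- "joint"
      e
    })
  } else {
    out <- lapply(scores, function(s) {
      fit <- fit_one(s)
      e <- assoc_estimate(s, stats::coef(fit)[[s]],
                          sqrt(stats::vcov(fit)[s, s]),
                          n_pairs = nrow(data))
      e$mode <- "univariate"
      e
    })
  }
  names(out) <- scores
  out
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools log odds ratios across cohorts with weights `1 / se^2`; the pooled
#' standard error is `sqrt(1 / sum(w))`. With a single estimate this is a
#' passthrough.
#'
#' @param estimates list of [assoc_estimate()] objects (or a data frame
#'   with `log_or` and `robust_se` columns).
#' @param label label for the pooled estimate.
#' @return pooled [assoc_estimate()].
#' @export
meta_fixed <- function(estimates, label = "pooled") {
  df <- if (is.data.frame(estimates)) estimates
        else do.call(rbind, lapply(estimates, as.data.frame))
  stopifnot(nrow(df) >= 1, all(is.finite(df$log_or)),
            all(df$robust_se > 0))
  w <- 1 / df$robust_se^2
  assoc_estimate(label, sum(w * df$log_or) / sum(w), sqrt(1 / sum(w)),
                 n_pairs = if (all(is.finite(df$n_pairs)))
                   sum(df$n_pairs) else NA_integer_)
}
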
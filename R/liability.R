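## Liability-threshold models on relative-pair cross tables: tetrachoric
## correlations, ACE/AE variance decomposition from the full-sib/cousin
## contrast (weighted least squares), and maximum-likelihood genetic
## correlation for ordinary and mutually exclusive trait pairs.
##
## Pair category probabilities are computed by an exact conditional
## factorization: conditional on the pair's shared bivariate factor (the
## family-level genetic + shared-environment component), the two relatives'
## liability vectors are independent bivariate normals, so each cell of the
## 3x3 / 4x4 cross table is a 2-D Gauss-Hermite average of closed-form
## bivariate-normal rectangle probabilities. Deterministic; accuracy set by
## the node count; rows sum to one by construction.

#' Cross-tabulate pair phenotype categories
#'
#' Builds the symmetric category cross table of an unordered relative pair
#' sample: counts are averaged over the two orderings, so the table is
#' symmetric and sums to the number of pairs. Optional per-pair weights
#' support family bootstrap resampling.
#'
#' @param cat_a,cat_b integer category codes (0-based) for the two pair
#'   members.
#' @param n_cat number of categories (2 for a single binary trait, 3 for an
#'   exclusive trait pair, 4 for two non-exclusive traits).
#' @param weights optional per-pair weights.
#' @return `n_cat` x `n_cat` symmetric numeric matrix of (possibly
#'   fractional) counts.
#' @export
pair_crosstable <- function(cat_a, cat_b, n_cat = max(cat_a, cat_b) + 1L,
                            weights = NULL) {
  stopifnot(length(cat_a) == length(cat_b))
  idx <- cat_a * n_cat + cat_b
  if (is.null(weights)) {
    cnt <- tabulate(idx + 1L, nbins = n_cat * n_cat)
  } else {
    cnt <- numeric(n_cat * n_cat)
    rs <- rowsum(weights, idx)
    cnt[as.integer(rownames(rs)) + 1L] <- rs
  }
  M <- matrix(cnt, n_cat, n_cat, byrow = TRUE)
  (M + t(M)) / 2
}

#' Tetrachoric correlation from a 2x2 pair table
#'
#' Solves \eqn{P(L_1 > z_1, L_2 > z_2; \rho)} = observed concordance for the
#' latent correlation by bracketed root finding (tolerance 1e-12 on
#' \eqn{\rho}), with thresholds taken from the table margins or from a
#' constrained prevalence. The standard error is the delta-method value
#' `sqrt(p11 (1-p11) / n) / phi2`, with `phi2` the bivariate normal density
#' at the thresholds (threshold uncertainty is ignored, appropriate when
#' the prevalence is constrained).
#'
#' @param tab 2x2 numeric matrix of pair counts, unaffected first
#'   (`tab[2, 2]` = both affected).
#' @param prevalence optional known prevalence fixing both thresholds.
#' @return object of class `tetrachoric`: list with `rho`, `se`, `z1`,
#'   `z2`, `p11`, `n`, `boundary` flag.
#' @export
tetrachoric <- function(tab, prevalence = NULL) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop("empty table")
  if (is.null(prevalence)) {
    p1 <- sum(tab[2L, ]) / n
    p2 <- sum(tab[, 2L]) / n
    if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
      stop("degenerate margins; tetrachoric undefined")
  } else {
    p1 <- p2 <- prevalence
  }
  z1 <- stats::qnorm(1 - p1)
  z2 <- stats::qnorm(1 - p2)
  p11 <- tab[2L, 2L] / n
  upper <- function(rho) pbvn(-z1, -z2, rho)  # P(L1 > z1, L2 > z2)
  boundary <- FALSE
  lo <- -1 + 1e-10; hi <- 1 - 1e-10
  f_lo <- upper(lo) - p11
  f_hi <- upper(hi) - p11
  if (f_lo >= 0) {          # p11 at or below its rho = -1 floor
    rho <- -1; boundary <- TRUE
  } else if (f_hi <= 0) {   # p11 at or above its rho = +1 ceiling
    rho <- 1; boundary <- TRUE
  } else {
    rho <- stats::uniroot(function(r) upper(r) - p11, c(lo, hi),
                          tol = 1e-12)$root
  }
  phi2 <- dbvn(z1, z2, rho)
  se <- if (phi2 > 0) sqrt(max(p11 * (1 - p11), 1e-300) / n) / phi2
        else NA_real_
  structure(list(rho = rho, se = se, z1 = z1, z2 = z2, p11 = p11, n = n,
                 boundary = boundary),
            class = "tetrachoric")
}

## bivariate normal density at (x, y) with correlation rho
dbvn <- function(x, y, rho) {
  om <- 1 - rho^2
  if (om <= 0) return(0)
  exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * om)) / (2 * pi * sqrt(om))
}

#' @export
print.tetrachoric <- function(x, ...) {
  cat(sprintf("tetrachoric rho = %.4f (SE %.4f), n = %g%s\n", x$rho, x$se,
              x$n, if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

## structural pair liability correlation implied by (a2, c2)
structural_r <- function(kinship, a2, c2 = 0, kappa_half = 0) {
  sh <- kinship_shares(kinship, kappa_half)
  sh$a * a2 + sh$c * c2
}

#' Liability-model fit container
#' @param x a `liability_fit` object.
#' @param ... unused.
#' @name liability_fit
NULL

new_liability_fit <- function(...) structure(list(...),
                                             class = "liability_fit")

#' @rdname liability_fit
#' @export
print.liability_fit <- function(x, ...) {
  cat(sprintf("%s model (%s estimator)\n", x$model, x$estimator))
  if (!is.null(x$a2))
    cat(sprintf("  a2 = %.4f  c2 = %.4f  e2 = %.4f\n", x$a2, x$c2, x$e2))
  if (!is.null(x$rg)) cat(sprintf("  rg = %.4f\n", x$rg))
  if (!is.null(x$fit_statistic))
    cat(sprintf("  fit statistic = %.4g (df = %g)\n", x$fit_statistic,
                x$df))
  if (!is.null(x$logLik))
    cat(sprintf("  log-likelihood = %.4f\n", x$logLik))
  if (!is.null(x$boot_ci)) {
    cat("  bootstrap 95% CI:\n")
    for (p in rownames(x$boot_ci))
      cat(sprintf("    %s: [%.4f, %.4f]\n", p, x$boot_ci[p, 1L],
                  x$boot_ci[p, 2L]))
  }
  invisible(x)
}

#' @rdname liability_fit
#' @export
coef.liability_fit <- function(object, ...) {
  # NULL components drop out of c() automatically
  c(a2 = object$a2, c2 = object$c2, e2 = object$e2, rg = object$rg)
}

#' ACE / AE heritability by weighted least squares
#'
#' Minimises the inverse-variance-weighted squared distance between the
#' observed full-sibling and cousin tetrachoric correlations and their
#' structural values `0.5 a2 + c2` and `0.125 a2`, subject to
#' `a2, c2 >= 0`, `a2 + c2 <= 1`. The AE model (2 statistics, 1 parameter)
#' leaves a 1-df fit statistic; the just-identified ACE model is solved
#' exactly, with boundary projection (and flag) when the unconstrained
#' solution leaves the parameter space (e.g. cousin correlation above a
#' quarter of the sibling one).
#'
#' @param tables named list with 2x2 pair tables `full_sib` and `cousin`
#'   (as from [pair_crosstable()]), or a named list of `tetrachoric`
#'   objects.
#' @param model `"AE"` or `"ACE"`.
#' @param prevalence optional prevalence constraint passed to
#'   [tetrachoric()].
#' @return a `liability_fit` with `a2`, `c2`, `e2`, the weighted
#'   `fit_statistic`, its `df`, and the per-kinship tetrachorics.
#' @export
fit_ace_wls <- function(tables, model = c("AE", "ACE"), prevalence = NULL) {
  model <- match.arg(model)
  stopifnot(all(c("full_sib", "cousin") %in% names(tables)))
  tet <- lapply(tables, function(t)
    if (inherits(t, "tetrachoric")) t else tetrachoric(t, prevalence))
  r <- vapply(tet, `[[`, numeric(1), "rho")[c("full_sib", "cousin")]
  se <- vapply(tet, `[[`, numeric(1), "se")[c("full_sib", "cousin")]
  w <- ifelse(is.finite(se) & se > 0, 1 / se^2, 0)
  if (all(w == 0)) w <- c(1, 1)  # equal weights fallback (exact inputs)
  s <- c(full_sib = 0.5, cousin = 0.125)
  boundary <- FALSE
  if (model == "AE") {
    a2 <- sum(w * s * r) / sum(w * s^2)
    if (a2 < 0 || a2 > 1) { a2 <- min(max(a2, 0), 1); boundary <- TRUE }
    c2 <- 0
    n_par <- 1L
  } else {
    a2 <- 8 * r[["cousin"]]
    c2 <- r[["full_sib"]] - 4 * r[["cousin"]]
    if (a2 < 0 || c2 < 0 || a2 + c2 > 1) {
      boundary <- TRUE
      if (c2 < 0) {          # collapse to AE
        a2 <- sum(w * s * r) / sum(w * s^2)
        c2 <- 0
      } else if (a2 < 0) {   # CE: only the sibling statistic informs c2
        a2 <- 0
        c2 <- min(max(r[["full_sib"]], 0), 1)
      }
      a2 <- min(max(a2, 0), 1)
      c2 <- min(c2, 1 - a2)
    }
    n_par <- 2L
  }
  fitted <- s * a2 + c(1, 0) * c2
  stat <- sum(w * (r - fitted)^2)
  new_liability_fit(model = model, estimator = "WLS",
                    a2 = a2, c2 = c2, e2 = 1 - a2 - c2, rg = NULL,
                    fit_statistic = stat, df = 2L - n_par,
                    boundary = boundary, tetrachoric = tet,
                    observed_r = r, weights = w)
}

## ---------------------------------------------------------------------
## cross-trait pair category probabilities via conditional factorization

# cached Gauss-Hermite rule
.famliab_gh <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) cache[[key]] <<- gauss_hermite(n)
    cache[[key]]
  }
})

#' Pair category probabilities for a cross-trait liability model
#'
#' Joint probabilities of the per-person phenotype categories for a relative
#' pair under the bivariate liability model: within-person cross-trait
#' correlation \eqn{r_g \sqrt{a^2_1 a^2_2} + r_e \sqrt{e^2_1 e^2_2}},
#' cross-person same-trait correlation `a_share * a2_t`, cross-person
#' cross-trait correlation \eqn{a\_share \cdot r_g \sqrt{a^2_1 a^2_2}}
#' (AE model). Categories are 0 = unaffected, 1 = trait 1, 2 = trait 2,
#' and, without exclusivity, 3 = both; under exclusivity trait 1 wins.
#'
#' @param rg genetic correlation in \[-1, 1\].
#' @param a2 length-2 additive variance shares.
#' @param z length-2 diagnostic thresholds.
#' @param kinship kinship class (sets the genetic sharing).
#' @param exclusive logical; mutually exclusive traits (3 categories) or
#'   not (4 categories).
#' @param re unique-environment cross-trait correlation (default 0).
#' @param nodes Gauss-Hermite nodes per dimension.
#' @return symmetric K x K probability matrix (K = 3 or 4) summing to 1.
#' @export
pair_category_probs <- function(rg, a2, z, kinship, exclusive = TRUE,
                                re = 0, nodes = 48L) {
  stopifnot(length(a2) == 2L, length(z) == 2L, abs(rg) <= 1)
  sh <- kinship_shares(kinship)$a
  sa <- sqrt(a2)
  rw <- rg * sa[1L] * sa[2L] + re * sqrt((1 - a2[1L]) * (1 - a2[2L]))
  ## shared (cross-person) covariance block and per-person residual
  B <- matrix(c(sh * a2[1L], sh * rg * sa[1L] * sa[2L],
                sh * rg * sa[1L] * sa[2L], sh * a2[2L]), 2L)
  W <- matrix(c(1, rw, rw, 1), 2L)
  R <- W - B
  if (min(eigen(W, symmetric = TRUE, only.values = TRUE)$values) < -1e-10 ||
      min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("parameter point implies a non-PSD liability correlation matrix")
  L <- tryCatch(t(chol(B + diag(1e-12, 2L))), error = function(e) NULL)
  if (is.null(L)) stop("shared covariance block not PSD")
  gh <- .famliab_gh(nodes)
  u <- rep(gh$nodes, times = nodes)
  v <- rep(gh$nodes, each = nodes)
  wgt <- rep(gh$weights, times = nodes) * rep(gh$weights, each = nodes)
  s1 <- L[1L, 1L] * u
  s2 <- L[2L, 1L] * u + L[2L, 2L] * v
  sd1 <- sqrt(max(R[1L, 1L], 1e-12))
  sd2 <- sqrt(max(R[2L, 2L], 1e-12))
  rc <- R[1L, 2L] / (sd1 * sd2)
  rc <- max(min(rc, 1), -1)
  h1 <- (z[1L] - s1) / sd1          # P(l1 <= z1 | s) = pnorm(h1)
  h2 <- (z[2L] - s2) / sd2
  p00 <- pbvn(h1, h2, rc)
  if (exclusive) {
    P1 <- stats::pnorm(h1, lower.tail = FALSE)   # trait 1 fires (wins)
    P2 <- stats::pnorm(h1) - p00                 # l1 below, l2 above
    Pg <- cbind(p00, P1, pmax(P2, 0))
  } else {
    p11 <- pbvn(-h1, -h2, rc)
    p10 <- stats::pnorm(h1, lower.tail = FALSE) - p11
    p01 <- stats::pnorm(h2, lower.tail = FALSE) - p11
    Pg <- cbind(p00, pmax(p10, 0), pmax(p01, 0), p11)
  }
  P <- crossprod(Pg, wgt * Pg)
  (P + t(P)) / 2
}

## calibrate the trait-2 threshold so the observed "trait 2" person-category
## probability is matched exactly under exclusivity (trait 1 masks trait 2)
calibrate_z2_exclusive <- function(p2_obs, z1, rw) {
  stopifnot(p2_obs > 0, p2_obs < stats::pnorm(z1))
  f <- function(z2) stats::pnorm(z1) - pbvn(z1, z2, rw) - p2_obs
  stats::uniroot(f, c(-10, 10), tol = 1e-12)$root
}

#' Maximum-likelihood genetic correlation from pair cross tables
#'
#' Multinomial likelihood over the pair phenotype categories, with the cell
#' probabilities given by [pair_category_probs()]. Marginal heritabilities
#' are fixed (two-stage estimation: supply the univariate estimates) and
#' thresholds are calibrated to the observed person-category margins --
#' exactly for non-exclusive traits, and accounting for the masking of
#' trait 2 by trait 1 for exclusive traits. Optimised over `rg` by golden
#' search; likelihood-ratio tests against `rg = 0` and `rg = 1` are
#' reported.
#'
#' @param tables named list of K x K pair cross tables (K = 3 exclusive,
#'   K = 4 not), with names among `full_sib`, `half_sib`, `cousin`.
#' @param a2 length-2 marginal additive variance shares (from univariate
#'   fits).
#' @param exclusive logical.
#' @param re unique-environment cross-trait correlation.
#' @param nodes Gauss-Hermite nodes per dimension.
#' @return a `liability_fit` with `rg`, `logLik`, and `lrt_rg0`,
#'   `lrt_rg1` (each a list with `statistic` and `p_value`).
#' @export
fit_rg_ml <- function(tables, a2, exclusive = TRUE, re = 0, nodes = 48L) {
  stopifnot(length(a2) == 2L, length(tables) >= 1)
  K <- if (exclusive) 3L else 4L
  for (t in tables) stopifnot(all(dim(as.matrix(t)) == K))
  kin <- names(tables)

  ## person-category margins pooled over kinship classes
  tot <- Reduce(`+`, lapply(tables, as.matrix))
  margin <- (rowSums(tot) + colSums(tot)) / (2 * sum(tot))
  if (exclusive) {
    p1 <- margin[2L]; p2 <- margin[3L]
  } else {
    p1 <- margin[2L] + margin[4L]; p2 <- margin[3L] + margin[4L]
  }
  if (p1 <= 0 || p2 <= 0) stop("a trait is absent from the tables")
  z1 <- stats::qnorm(1 - p1)

  loglik <- function(rg) {
    rw <- rg * sqrt(prod(a2)) + re * sqrt(prod(1 - a2))
    if (abs(rw) >= 1) return(-Inf)
    z2 <- if (exclusive) {
      tryCatch(calibrate_z2_exclusive(p2, z1, rw),
               error = function(e) NA_real_)
    } else stats::qnorm(1 - p2)
    if (is.na(z2)) return(-Inf)
    ll <- 0
    for (k in seq_along(tables)) {
      P <- tryCatch(pair_category_probs(rg, a2, c(z1, z2), kin[k],
                                        exclusive, re, nodes),
                    error = function(e) NULL)
      if (is.null(P)) return(-Inf)  # non-PSD candidate: reject step
      M <- as.matrix(tables[[k]])
      ll <- ll + sum(M * log(pmax(P, 1e-300)))
    }
    ll
  }

  opt <- stats::optimize(loglik, c(-0.999, 0.999), maximum = TRUE,
                         tol = 1e-6)
  rg_hat <- opt$maximum
  ll_hat <- opt$objective
  ll0 <- loglik(0)
  ll1 <- loglik(1 - 1e-9)
  lrt <- function(ll_c) {
    stat <- max(0, 2 * (ll_hat - ll_c))
    list(statistic = stat, p_value = stats::pchisq(stat, 1L,
                                                   lower.tail = FALSE))
  }
  new_liability_fit(model = if (exclusive) "exclusive-rg" else "cross-rg",
                    estimator = "ML", a2 = NULL, c2 = NULL, e2 = NULL,
                    rg = rg_hat, logLik = ll_hat,
                    marginal_a2 = a2, thresholds = c(z1 = z1, p2 = p2),
                    lrt_rg0 = lrt(ll0), lrt_rg1 = lrt(ll1),
                    loglik_fn = loglik)
}

#' Family-clustered bootstrap percentile confidence intervals
#'
#' Resamples families with replacement, reweights the per-observation rows
#' accordingly, recomputes the statistic, and returns percentile 95%
#' intervals. Reproducible given a seed.
#'
#' @param stat_fn function of one argument (a per-row weight vector) that
#'   rebuilds the cross tables / datasets with those weights and returns a
#'   named numeric vector of statistics.
#' @param family_ids per-row family identifiers.
#' @param n_boot number of replicates (the register analyses use 1000).
#' @param seed optional integer seed.
#' @param level confidence level.
#' @return list with `ci` (matrix, one row per statistic), `replicates`
#'   (n_boot x statistics), `n_boot`.
#' @export
bootstrap_ci <- function(stat_fn, family_ids, n_boot = 1000L, seed = NULL,
                         level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  fam <- factor(family_ids)
  nf <- nlevels(fam)
  fi <- as.integer(fam)
  first <- stat_fn(rep(1, length(fi)))
  reps <- matrix(NA_real_, n_boot, length(first),
                 dimnames = list(NULL, names(first)))
  for (b in seq_len(n_boot)) {
    w_f <- tabulate(sample.int(nf, nf, replace = TRUE), nbins = nf)
    reps[b, ] <- stat_fn(w_f[fi])
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(reps, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, type = 7))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, replicates = reps, n_boot = n_boot, estimate = first)
}

#' Compare nested liability-model fits
#'
#' WLS fits are compared by the difference of weighted fit statistics with
#' degrees of freedom equal to the parameter difference; ML fits by the
#' likelihood-ratio statistic. When the constrained parameter sits on the
#' boundary of its space (e.g. testing `c2 = 0`), the usual chi-square
#' reference is conservative; the 50:50 mixture p-value (half the
#' chi-square tail) is reported alongside and flagged.
#'
#' @param fit_full,fit_constrained `liability_fit` objects from the same
#'   estimator.
#' @param df degrees of freedom of the comparison (default 1).
#' @param boundary is the constrained parameter on its boundary?
#' @return list with `statistic`, `df`, `p_value`, `p_value_mixture`,
#'   `boundary`.
#' @export
compare_models <- function(fit_full, fit_constrained, df = 1L,
                           boundary = FALSE) {
  if (!is.null(fit_full$logLik) && !is.null(fit_constrained$logLik)) {
    stat <- max(0, 2 * (fit_full$logLik - fit_constrained$logLik))
  } else {
    stat <- max(0, fit_constrained$fit_statistic - fit_full$fit_statistic)
  }
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p,
       p_value_mixture = if (boundary) p / 2 else p,
       boundary = boundary)
}

#' Bootstrap test for equality of two genetic correlations
#'
#' Two-sided percentile test on the (paired, when replicates come from the
#' same family resampling) bootstrap distribution of `rg1 - rg2`.
#'
#' @param rg1_boot,rg2_boot bootstrap replicate vectors of the two
#'   estimates (equal length; paired by replicate).
#' @return list with the observed mean difference, its bootstrap SE, and
#'   the two-sided `p_value`.
#' @export
rg_difference_test <- function(rg1_boot, rg2_boot) {
  stopifnot(length(rg1_boot) == length(rg2_boot))
  d <- rg1_boot - rg2_boot
  d <- d[is.finite(d)]
  B <- length(d)
  p <- 2 * min((1 + sum(d <= 0)) / (B + 1), (1 + sum(d >= 0)) / (B + 1))
  list(mean_diff = mean(d), se = stats::sd(d), p_value = min(p, 1),
       n_boot = B)
}
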
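## Low-level multivariate-normal numerics used by the liability models:
## Gaussian quadrature rules (Golub-Welsch) and the standard bivariate
## normal CDF (Drezner-Wesolowsky with Genz's high-correlation expansion).

#' Gauss-Legendre quadrature rule
#'
#' Nodes and weights for \eqn{\int_{-1}^{1} f(x)\,dx} via the Golub-Welsch
#' eigen decomposition of the Jacobi matrix.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`, each length `n`.
#' @keywords internal
gauss_legendre <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1L, idx]^2)
}

#' Gauss-Hermite quadrature rule (probabilists' weight)
#'
#' Nodes and weights such that \eqn{\sum w_i f(x_i) \approx E[f(Z)]} for
#' standard normal Z; weights sum to 1.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`.
#' @keywords internal
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  b <- sqrt(i)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = e$vectors[1L, idx]^2)
}

# cached 24-point Gauss-Legendre rule for the bvn integrand
.famliab_gl24 <- local({
  r <- NULL
  function() {
    if (is.null(r)) r <<- gauss_legendre(24L)
    r
  }
})

## scalar P(X > h, Y > k) for standard bivariate normal with correlation r;
## transcription of Genz's BVND hybrid algorithm.
.bvnd_upper <- function(h, k, r) {
  if (abs(r) >= 1) {
    if (r >= 1) return(stats::pnorm(-max(h, k)))
    return(max(0, 1 - stats::pnorm(h) - stats::pnorm(k)))
  }
  gl <- .famliab_gl24()
  x <- gl$nodes; w <- gl$weights
  hk <- h * k
  bvn <- 0
  if (abs(r) < 0.925) {
    if (abs(r) > 0) {
      hs <- (h * h + k * k) / 2
      asr <- asin(r)
      sn <- sin(asr * (x + 1) / 2)
      bvn <- sum(w * exp((sn * hk - hs) / (1 - sn * sn))) * asr / (4 * pi)
    }
    bvn + stats::pnorm(-h) * stats::pnorm(-k)
  } else {
    if (r < 0) {
      k <- -k
      hk <- -hk
    }
    as_ <- (1 - r) * (1 + r)
    a <- sqrt(as_)
    bs <- (h - k)^2
    cc <- (4 - hk) / 8
    d <- (12 - hk) / 16
    asr <- -(bs / as_ + hk) / 2
    if (asr > -100)
      bvn <- a * exp(asr) * (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 +
                               cc * d * as_ * as_ / 5)
    if (-hk < 100) {
      b <- sqrt(bs)
      bvn <- bvn - exp(-hk / 2) * sqrt(2 * pi) * stats::pnorm(-b / a) * b *
        (1 - cc * bs * (1 - d * bs / 5) / 3)
    }
    a2 <- a / 2
    xs <- (a2 * (x + 1))^2
    rs <- sqrt(1 - xs)
    asr2 <- -(bs / xs + hk) / 2
    keep <- asr2 > -100
    if (any(keep)) {
      term <- a2 * exp(asr2[keep]) *
        (exp(-hk * (1 - rs[keep]) / (2 * (1 + rs[keep]))) / rs[keep] -
           (1 + cc * xs[keep] * (1 + d * xs[keep])))
      bvn <- bvn + sum(w[keep] * term)
    }
    bvn <- -bvn / (2 * pi)
    if (r > 0) {
      bvn + stats::pnorm(-max(h, k))
    } else {
      bvn <- -bvn
      if (k > h) bvn <- bvn + stats::pnorm(k) - stats::pnorm(h)
      max(0, bvn)
    }
  }
}

#' Standard bivariate normal CDF
#'
#' \eqn{P(X \le h, Y \le k)} for a standard bivariate normal vector with
#' correlation `rho`. Vectorised over `h` and `k` (recycled); `rho` is a
#' scalar. Accuracy is near machine precision (Drezner-Wesolowsky quadrature
#' for \eqn{|\rho| < 0.925}, Genz's asymptotic expansion above).
#'
#' @param h,k upper integration limits (numeric vectors).
#' @param rho scalar correlation in \[-1, 1\].
#' @return numeric vector of probabilities.
#' @export
#' @examples
#' pbvn(0, 0, 0.5)            # 1/4 + asin(0.5)/(2*pi) = 1/3
#' pbvn(c(-1, 0, 1), 0.3, 0)  # independence: pnorm(h) * pnorm(0.3)
pbvn <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho), abs(rho) <= 1)
  n <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  if (abs(rho) < 0.925) {
    # vectorised fast path of the quadrature branch, on upper orthant of (-h,-k)
    gl <- .famliab_gl24()
    sn <- sin(asin(rho) * (gl$nodes + 1) / 2)   # length 24
    hs <- (h * h + k * k) / 2
    hk <- h * k
    # outer: n x 24
    z <- (outer(hk, sn) - hs) / rep(1 - sn * sn, each = n)
    corr <- as.vector(exp(z) %*% gl$weights) * asin(rho) / (4 * pi)
    out <- stats::pnorm(h) * stats::pnorm(k) + corr
    pmin(pmax(out, 0), 1)
  } else {
    vapply(seq_along(h), function(i) .bvnd_upper(-h[i], -k[i], rho),
           numeric(1))
  }
}
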
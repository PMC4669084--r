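# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Studentized-range CDF by direct numerical integration (k groups, nu df),
# independent of stats::ptukey.
ptukey_integrate <- function(q, k, nu) {
  inner <- function(s) {
    # P(range of k std normals <= q*s)
    vapply(s, function(si) {
      f <- function(z) {
        k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * si))^(k - 1)
      }
      stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  # density of s = chi_nu / sqrt(nu)
  dsc <- function(s) {
    exp(nu / 2 * log(nu) + (nu - 1) * log(s) - nu * s^2 / 2 -
          lgamma(nu / 2) - (nu / 2 - 1) * log(2))
  }
  stats::integrate(function(s) dsc(s) * inner(s), 0, Inf,
                   rel.tol = 1e-8)$value
}

# SVD-per-component PLS2: w = leading left singular vector of X'Y, then the
# usual scores/loadings and deflation. Algebraically the NIPALS fixed point,
# reached by a different route.
svd_pls2 <- function(x, y, n_components, scale = TRUE) {
  xc <- base::scale(x, scale = scale)
  yc <- base::scale(y, scale = scale)
  W <- NULL; Tm <- NULL; C <- NULL; P <- NULL
  for (i in seq_len(n_components)) {
    s <- svd(crossprod(xc, yc))
    w <- s$u[, 1]
    flip <- sign(w[which.max(abs(w))])
    w <- flip * w
    tt <- xc %*% w
    cc <- crossprod(yc, tt) / sum(tt^2)
    pp <- crossprod(xc, tt) / sum(tt^2)
    xc <- xc - tt %*% t(pp)
    yc <- yc - tt %*% t(cc)
    W <- cbind(W, w); Tm <- cbind(Tm, tt); C <- cbind(C, cc); P <- cbind(P, pp)
  }
  list(weights = W, scores = Tm, y_loadings = C, x_loadings = P)
}

# Sequential sums of squares by explicit nested least squares (QR), not
# stats::anova.
sequential_ss <- function(y, terms_list) {
  rss <- function(mm) {
    fit <- qr.fitted(qr(mm), y)
    sum((y - fit)^2)
  }
  n <- length(y)
  mm <- matrix(1, n, 1)
  out <- numeric(length(terms_list))
  prev <- rss(mm)
  for (i in seq_along(terms_list)) {
    mm <- cbind(mm, terms_list[[i]])
    cur <- rss(mm)
    out[i] <- prev - cur
    prev <- cur
  }
  c(out, residual = prev)
}
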
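# Compact (mu/mu_w, lambda) CMA-ES in a unit-box-normalized space.
# Derivative-free global search used for the per-block warm-up of the
# joint fit; a Levenberg-Marquardt polish follows. Out-of-box proposals
# are evaluated at their projection with a quadratic penalty. Uses the
# caller's RNG stream (wrap in with_seed for determinism).
.cma_es <- function(fn, x0, lower, upper, sigma0 = 0.3, maxgen = 300,
                    lambda = NULL, tol_stagnation = 80) {
  n <- length(x0)
  scale <- upper - lower
  to_z <- function(x) (x - lower) / scale
  from_z <- function(z) lower + z * scale
  fz <- function(z) {
    zc <- pmin(pmax(z, 0), 1)
    fn(from_z(zc)) + 1e4 * sum((z - zc)^2)
  }
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- to_z(x0)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n); C <- diag(n)
  invsqrtC <- diag(n)
  eigeneval <- 0; counteval <- 1
  # the start point is a candidate too: the search never returns anything
  # worse than what it was given
  best_f <- fz(xmean); best_x <- xmean
  stagn <- 0
  for (gen in seq_len(maxgen)) {
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)
    X <- xmean + sigma * Y
    f <- apply(X, 2, fz)
    counteval <- counteval + lambda
    ord <- order(f)
    improved <- is.finite(f[ord[1]]) &&
      (!is.finite(best_f) || f[ord[1]] < best_f - 1e-12 * abs(best_f))
    if (improved) {
      best_f <- f[ord[1]]; best_x <- X[, ord[1]]; stagn <- 0
    } else stagn <- stagn + 1
    if (stagn > tol_stagnation) break
    xold <- xmean
    xmean <- drop(X[, ord[seq_len(mu)], drop = FALSE] %*% w)
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% (xmean - xold)) / sigma
    hsig <- sum(ps^2) / (1 - (1 - cs)^(2 * counteval / lambda)) / n <
      2 + 4 / (n + 1)
    pc <- (1 - cc) * pc +
      hsig * sqrt(cc * (2 - cc) * mueff) * (xmean - xold) / sigma
    artmp <- (X[, ord[seq_len(mu)], drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (counteval - eigeneval > lambda / (c1 + cmu) / n / 10) {
      eigeneval <- counteval
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eg$values, 1e-20))
      B <- eg$vectors
      invsqrtC <- B %*% (t(B) / D)
    }
    if (sigma < 1e-9) break
  }
  zc <- pmin(pmax(best_x, 0), 1)
  list(par = from_z(zc), value = best_f, evals = counteval)
}
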
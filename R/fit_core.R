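## Nonlinear least-squares engines for exponential relaxometry models.
##
## All fits use variable projection: for a trial decay constant the linear
## amplitudes have a closed-form least-squares solution, so each model
## reduces to a 1-D optimization over the rate. A coarse log-spaced grid
## (vectorized across pixels) provides a deterministic global
## initialization; Brent refinement then polishes the winning interval to
## ~1e-10 relative. This is equivalent to log-linear initialization
## followed by Gauss-Newton for clean data, but is robust to the Rician
## floor and to polarity ambiguity on magnitude IR data.

default_time_grid <- function(n = 80, lo = 1, hi = 10000) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# SSR of y ~ b * exp(-t/tc) for a single pixel; returns list(ssr, b)
ssr_monoexp <- function(tc, t, y) {
  x <- exp(-t / tc)
  xx <- sum(x * x)
  b <- sum(x * y) / xx
  list(ssr = sum((y - b * x)^2), b = b)
}

# SSR of y ~ a + b * exp(-t/tc) for a single pixel
ssr_offset_exp <- function(tc, t, y) {
  x <- exp(-t / tc)
  n <- length(y)
  sx <- sum(x); sxx <- sum(x * x); sy <- sum(y); sxy <- sum(x * y)
  det <- n * sxx - sx * sx
  if (abs(det) < 1e-300) return(list(ssr = Inf, a = NA_real_, b = NA_real_))
  a <- (sxx * sy - sx * sxy) / det
  b <- (n * sxy - sx * sy) / det
  list(ssr = sum((y - a - b * x)^2), a = a, b = b)
}

refine_1d <- function(obj, bracket) {
  optimize(obj, interval = bracket, tol = 1e-11 * mean(bracket))
}

# Mono-exponential decay fit, vectorized coarse stage.
# Y: nframes x npix matrix (frames in ascending t order), t: times (ms).
# offset: fit y = a + b exp(-t/tc) instead of y = b exp(-t/tc).
fit_exp_core <- function(Y, t, grid = default_time_grid(),
                         offset = FALSE) {
  nf <- nrow(Y); npix <- ncol(Y)
  X <- exp(-outer(grid, t, function(g, tt) tt / g))  # G x nf
  best_ssr <- rep(Inf, npix)
  best_g <- rep(1L, npix)
  yTy <- colSums(Y * Y)
  if (!offset) {
    XY <- X %*% Y                      # G x npix
    xx <- rowSums(X * X)
    for (g in seq_along(grid)) {
      ssr <- yTy - XY[g, ]^2 / xx[g]
      upd <- ssr < best_ssr
      best_ssr[upd] <- ssr[upd]
      best_g[upd] <- g
    }
  } else {
    sy <- colSums(Y)
    XY <- X %*% Y
    sx <- rowSums(X); sxx <- rowSums(X * X)
    for (g in seq_along(grid)) {
      det <- nf * sxx[g] - sx[g]^2
      a <- (sxx[g] * sy - sx[g] * XY[g, ]) / det
      b <- (nf * XY[g, ] - sx[g] * sy) / det
      ssr <- yTy - a * sy - b * XY[g, ]
      upd <- ssr < best_ssr
      best_ssr[upd] <- ssr[upd]
      best_g[upd] <- g
    }
  }
  tc <- amp <- off <- rss <- rep(NA_real_, npix)
  conv <- rep(FALSE, npix)
  for (p in seq_len(npix)) {
    y <- Y[, p]
    if (all(!is.finite(y)) || all(y <= 0)) next
    g <- best_g[p]
    lo <- grid[max(1L, g - 1L)]
    hi <- grid[min(length(grid), g + 1L)]
    if (!offset) {
      opt <- refine_1d(function(tc) ssr_monoexp(tc, t, y)$ssr, c(lo, hi))
      sol <- ssr_monoexp(opt$minimum, t, y)
      amp[p] <- sol$b; off[p] <- 0
    } else {
      opt <- refine_1d(function(tc) ssr_offset_exp(tc, t, y)$ssr,
                       c(lo, hi))
      sol <- ssr_offset_exp(opt$minimum, t, y)
      amp[p] <- sol$b; off[p] <- sol$a
    }
    tc[p] <- opt$minimum
    rss[p] <- max(sol$ssr, 0)
    conv[p] <- is.finite(tc[p]) && amp[p] > 0
  }
  list(tc = tc, amplitude = amp, offset = off, rss = rss,
       converged = conv)
}

# Inversion-recovery fit with polarity restoration on magnitude data.
# Model (signed): y = A - B exp(-t/tc). Candidate flip index k negates
# the first k frames (ascending t); best-RSS candidate wins, ties broken
# toward the smaller flip index. Candidates with a physically valid
# inversion-recovery shape (A > 0, B > A) are preferred: under noise a
# spurious no-flip candidate with B < A can otherwise edge out the true
# solution on residual alone while implying an impossible recovery.
fit_ir_core <- function(Y, t, grid = default_time_grid()) {
  nf <- nrow(Y); npix <- ncol(Y)
  X <- exp(-outer(grid, t, function(g, tt) tt / g))
  sx <- rowSums(X); sxx <- rowSums(X * X)
  best_ssr <- rep(Inf, npix)
  best_g <- rep(1L, npix)
  best_k <- rep(0L, npix)
  valid_ssr <- rep(Inf, npix)
  valid_g <- rep(1L, npix)
  valid_k <- rep(0L, npix)
  any_valid <- rep(FALSE, npix)
  for (k in 0:nf) {
    s <- c(rep(-1, k), rep(1, nf - k))
    Yk <- Y * s
    yTy <- colSums(Yk * Yk)
    sy <- colSums(Yk)
    XY <- X %*% Yk
    for (g in seq_along(grid)) {
      det <- nf * sxx[g] - sx[g]^2
      a <- (sxx[g] * sy - sx[g] * XY[g, ]) / det
      b <- (nf * XY[g, ] - sx[g] * sy) / det
      ssr <- pmax(yTy - a * sy - b * XY[g, ], 0)
      upd <- ssr < best_ssr - 1e-15 * (1 + yTy)
      best_ssr[upd] <- ssr[upd]
      best_g[upd] <- g
      best_k[upd] <- k
      ok <- a > 0 & -b > a                  # A > 0, B > A
      updv <- ok & ssr < valid_ssr - 1e-15 * (1 + yTy)
      valid_ssr[updv] <- ssr[updv]
      valid_g[updv] <- g
      valid_k[updv] <- k
      any_valid <- any_valid | ok
    }
  }
  best_g[any_valid] <- valid_g[any_valid]
  best_k[any_valid] <- valid_k[any_valid]
  tc <- A <- B <- rss <- rep(NA_real_, npix)
  conv <- rep(FALSE, npix)
  for (p in seq_len(npix)) {
    y <- Y[, p]
    if (all(!is.finite(y))) next
    k <- best_k[p]
    yk <- y * c(rep(-1, k), rep(1, nf - k))
    g <- best_g[p]
    lo <- grid[max(1L, g - 1L)]
    hi <- grid[min(length(grid), g + 1L)]
    opt <- refine_1d(function(tc) ssr_offset_exp(tc, t, yk)$ssr,
                     c(lo, hi))
    sol <- ssr_offset_exp(opt$minimum, t, yk)
    tc[p] <- opt$minimum
    A[p] <- sol$a
    B[p] <- -sol$b                     # y = a + b x with B = -b
    rss[p] <- max(sol$ssr, 0)
    conv[p] <- is.finite(tc[p]) && B[p] > 0
  }
  list(tc = tc, A = A, B = B, flip_index = best_k, rss = rss,
       converged = conv)
}
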
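# Shared fixtures built in code.

# Single-compartment scene of given size with uniform truth.
uniform_truth <- function(t1, t2, nx = 1, ny = 1, pixel_size = 1) {
  ground_truth_maps(matrix(1L, nx, ny), matrix(t1, nx, ny),
                    matrix(t2, nx, ny), pixel_size)
}

# Independent normal-equations least-squares oracle for the relaxivity
# plane (rates in 1/s from ms inputs).
normal_equations_oracle <- function(df, t_col) {
  X <- cbind(1, df$ni_mM, df$agarose_pct)
  drop(solve(t(X) %*% X, t(X) %*% (1000 / df[[t_col]])))
}

# Dense grid-search oracle for the no-offset mono-exponential fit.
grid_search_t2 <- function(t, y, grid = seq(1, 300, by = 0.01)) {
  best <- Inf
  best_tc <- NA_real_
  for (tc in grid) {
    x <- exp(-t / tc)
    b <- sum(x * y) / sum(x * x)
    ssr <- sum((y - b * x)^2)
    if (ssr < best) {
      best <- ssr
      best_tc <- tc
    }
  }
  best_tc
}

# Exhaustive polarity + grid oracle for the signed IR model
# y = A - B exp(-t/tc) on magnitude data.
ir_enumeration_oracle <- function(t, y, grid = seq(5, 5000, by = 2.5)) {
  nf <- length(y)
  best <- list(ssr = Inf)
  for (k in 0:nf) {
    yk <- y * c(rep(-1, k), rep(1, nf - k))
    for (tc in grid) {
      x <- exp(-t / tc)
      fit <- lm(yk ~ x)
      ssr <- sum(resid(fit)^2)
      if (ssr < best$ssr - 1e-12) {
        best <- list(ssr = ssr, k = k, tc = tc)
      }
    }
  }
  best
}

molli_default_stack <- function(t1, t2 = 45, ...) {
  simulate_molli(uniform_truth(t1, t2), protocol_molli(...))
}
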
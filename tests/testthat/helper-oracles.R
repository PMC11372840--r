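# Independent brute-force oracles. These deliberately re-derive results with
# plain loops and closed forms, sharing no code path with the package.

# Residual ln(gamma) by an undamped dense fixed-point iteration written
# directly from the segment-interaction equations. Profiles are sigma_profile
# objects; x mole fractions; T in K.
oracle_residual <- function(profiles, x, T, tol = 1e-14, maxit = 20000L) {
  pars <- cosmosac_params()
  grid <- sigma_grid()
  n <- 51L * 3L
  sig <- rep(grid, 3L)
  cls <- rep(1:3, each = 51L)
  chb_of <- function(ci, cj, si, sj) {
    if (si * sj >= 0) return(0)
    if (ci == 2 && cj == 2) return(pars$c_hb_ohoh)
    if (ci == 3 && cj == 3) return(pars$c_hb_otot)
    if ((ci == 2 && cj == 3) || (ci == 3 && cj == 2)) return(pars$c_hb_ohot)
    0
  }
  c_es <- pars$A_ES + pars$B_ES / T^2
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dW <- c_es * (sig[i] + sig[j])^2 -
        chb_of(cls[i], cls[j], sig[i], sig[j]) * (sig[i] - sig[j])^2
      K[i, j] <- exp(-dW / (pars$R_kcal * T))
    }
  }
  solve_gam <- function(p) {
    gam <- rep(1, n)
    for (it in seq_len(maxit)) {
      gnew <- 1 / as.vector(K %*% (p * gam))
      gnew <- 0.5 * (gnew + gam)          # plain average for stability
      if (max(abs(gnew - gam)) < tol) return(gnew)
      gam <- gnew
    }
    stop("oracle gamma iteration did not converge")
  }
  A <- vapply(profiles, function(pr) pr$area, numeric(1))
  p_i <- lapply(profiles, function(pr) as.vector(pr$values) / pr$area)
  p_mix <- (x[1] * A[1] * p_i[[1]] + x[2] * A[2] * p_i[[2]]) / sum(x * A)
  g_mix <- solve_gam(p_mix)
  vapply(1:2, function(i) {
    g_pure <- solve_gam(p_i[[i]])
    (A[i] / pars$a_eff) * sum(p_i[[i]] * (log(g_mix) - log(g_pure)))
  }, numeric(1))
}

# Common-tangent construction of the symmetric-Margules binodal from a dense
# Delta g_mix grid: lower convex hull by explicit slope comparison.
oracle_common_tangent <- function(A, n_grid = 1e6) {
  xs <- seq(1 / n_grid, 1 - 1 / n_grid, length.out = n_grid)
  g <- xs * log(xs) + (1 - xs) * log(1 - xs) + A * xs * (1 - xs)
  hull <- integer(length(xs))
  m <- 0L
  for (i in seq_along(xs)) {
    while (m >= 2L) {
      a <- hull[m - 1L]
      b <- hull[m]
      s_ab <- (g[b] - g[a]) / (xs[b] - xs[a])
      s_ai <- (g[i] - g[a]) / (xs[i] - xs[a])
      if (s_ab < s_ai) break
      m <- m - 1L
    }
    m <- m + 1L
    hull[m] <- i
  }
  hull <- hull[seq_len(m)]
  jump <- which(diff(hull) > 1L)
  if (length(jump) == 0L) return(NULL)
  c(xs[hull[jump[1]]], xs[hull[jump[1] + 1L]])
}

# Dense second-difference scan of Delta g_mix for the spinodal of the
# symmetric Margules model.
oracle_spinodal_scan <- function(A, n_grid = 1e6) {
  xs <- seq(1 / n_grid, 1 - 1 / n_grid, length.out = n_grid)
  g <- xs * log(xs) + (1 - xs) * log(1 - xs) + A * xs * (1 - xs)
  d2 <- diff(g, differences = 2)
  sgn <- sign(d2)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  xs[flips + 1L]
}
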
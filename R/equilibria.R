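#' Fusion Gibbs energy of the pure crystalline drug
#'
#' Molar Gibbs-energy difference between the pure supercooled liquid and the
#' crystal at temperature `T`, from the melting properties with the full
#' heat-capacity integrals. With \eqn{\Delta_{fus} c_p = a + bT} (J/(K mol)):
#' \deqn{\Delta_{fus} g(T) = \Delta_{fus} h \left(1 - \frac{T}{T_m}\right)
#'  - \int_T^{T_m} \Delta_{fus} c_p \, dT'
#'  + T \int_T^{T_m} \frac{\Delta_{fus} c_p}{T'} \, dT'}
#' It vanishes exactly at `T = T_m`.
#'
#' @param api A [component()] carrying fusion properties.
#' @param T Temperature in K.
#' @return \eqn{\Delta_{fus} g} in kJ/mol (vectorized over `T`).
#' @export
delta_fus_g <- function(api, T) {
  if (!is.finite(api$Tm) || !is.finite(api$dHfus)) {
    stop("component '", api$name, "' has no fusion properties", call. = FALSE)
  }
  stopifnot(all(T > 0))
  Tm <- api$Tm
  a <- api$dCp_a
  b <- api$dCp_b
  api$dHfus * (1 - T / Tm) -
    (a * (Tm - T) + b / 2 * (Tm^2 - T^2)) / 1000 +
    T * (a * log(Tm / T) + b * (Tm - T)) / 1000
}

#' Mole/weight fraction conversion for a binary drug-polymer mixture
#'
#' @param x_api API mole fraction (vectorized).
#' @param M_api,M_poly Molar masses in g/mol.
#' @return The API weight fraction (resp. mole fraction).
#' @export
x_to_w <- function(x_api, M_api, M_poly) {
  x_api * M_api / (x_api * M_api + (1 - x_api) * M_poly)
}

#' @rdname x_to_w
#' @param w_api API weight fraction (vectorized).
#' @export
w_to_x <- function(w_api, M_api, M_poly) {
  (w_api / M_api) / (w_api / M_api + (1 - w_api) / M_poly)
}

# Total ln(gamma) pair at composition x = (x1, 1-x1), reusing a residual
# workspace built once per temperature.
lngamma_pair_ws <- function(ws, components, x1, config) {
  x <- c(x1, 1 - x1)
  res <- lngamma_residual_ws(ws, x)
  comb <- switch(config$combinatorial,
    none = c(0, 0),
    sg = lngamma_sg(components, x, config),
    fv = lngamma_fv(components, x))
  dsp <- if (config$dispersion) {
    dispersion_A_value(components, ws$T, config) * c(x[2]^2, x[1]^2)
  } else {
    c(0, 0)
  }
  as.numeric(res) + comb + dsp
}

# ln activities (ln x_i gamma_i) at x1; safe at the composition edges.
lnact_ws <- function(ws, components, x1, config) {
  lg <- lngamma_pair_ws(ws, components, x1, config)
  c(log(x1) + lg[1], log(1 - x1) + lg[2])
}

# Reduced mixing Gibbs energy g(x) = Delta g_mix / RT.
gmix_ws <- function(ws, components, x1, config) {
  la <- lnact_ws(ws, components, x1, config)
  x1 * la[1] + (1 - x1) * la[2]
}

# dg/dx1 = ln a1 - ln a2 (exact for a binary via Gibbs-Duhem).
dgmix_ws <- function(ws, components, x1, config) {
  la <- lnact_ws(ws, components, x1, config)
  la[1] - la[2]
}

#' Solid-liquid equilibrium: drug solubility at one temperature
#'
#' Finds the API mole fraction satisfying
#' \eqn{\ln(x_{API}\gamma_{API}) = -\Delta_{fus} g / (RT)} by a bracketed
#' root search over `(1e-12, 1]`; when several roots exist the largest
#' (closest to ideal) is returned with a warning.
#'
#' @param components List of two [component()]s, the crystallizable API
#'   first.
#' @param config A [model_config()].
#' @param T Temperature in K (must be below the API melting point).
#' @param n_scan Number of scan points used for bracketing.
#' @return API mole fraction, with attribute `residual` (the equation
#'   residual at the root); `NA` with a warning when no root exists.
#' @export
solve_sle <- function(components, config, T, n_scan = 200L) {
  check_binary(components, c(0.5, 0.5))
  api <- components[[1]]
  if (!is.finite(api$Tm)) {
    stop("first component must be the crystallizable API", call. = FALSE)
  }
  if (T >= api$Tm) {
    stop(sprintf("T = %.2f K is not below the API melting point %.2f K",
                 T, api$Tm), call. = FALSE)
  }
  rhs <- delta_fus_g(api, T) * 1000 / (RGAS * T)
  ws <- residual_workspace(components, T, config)
  f <- function(x1) {
    log(x1) + lngamma_pair_ws(ws, components, x1, config)[1] + rhs
  }
  xs <- unique(sort(c(10^seq(-12, -2, length.out = 40L),
                      seq(0.01, 1, length.out = n_scan))))
  fv <- vapply(xs, f, numeric(1))
  sgn <- sign(fv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- xs[fv == 0]
  for (i in flips) {
    r <- stats::uniroot(f, lower = xs[i], upper = xs[i + 1L],
                        tol = 1e-14)
    roots <- c(roots, r$root)
  }
  if (length(roots) == 0L) {
    warning(sprintf(
      "no solubility at T = %.2f K: SLE residual has no sign change (min |f| = %.3g)",
      T, min(abs(fv))), call. = FALSE)
    return(structure(NA_real_, residual = NA_real_))
  }
  if (length(roots) > 1L) {
    warning(sprintf(
      "multiple SLE roots at T = %.2f K (%s); returning the largest",
      T, paste(signif(roots, 6), collapse = ", ")), call. = FALSE)
  }
  x <- max(roots)
  structure(x, residual = f(x))
}

# Lower convex hull of a sampled curve; returns indices of hull points.
lower_hull <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      a <- hull[m - 1L]; b <- hull[m]
      # keep b only while it lies strictly below the chord a -> i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) > 0) {
        break
      }
      m <- m - 1L
    }
    m <- m + 1L
    hull[m] <- i
  }
  hull[seq_len(m)]
}

# Miscibility-gap bracket(s) from a g(x) scan: consecutive lower-hull points
# with skipped interior points. Returns a list of c(x_left, x_right).
gap_brackets <- function(xs, gs) {
  h <- lower_hull(xs, gs)
  gaps <- which(diff(h) > 1L)
  lapply(gaps, function(i) c(xs[h[i]], xs[h[i + 1L]]))
}

# Spinodal interval(s): sign changes of the second derivative of g.
curvature_ws <- function(ws, components, x1, config, h = 1e-6) {
  (dgmix_ws(ws, components, x1 + h, config) -
     dgmix_ws(ws, components, x1 - h, config)) / (2 * h)
}

#' Liquid-liquid equilibrium: one binodal tie-line
#'
#' Searches for a pair of amorphous-phase compositions with equal component
#' activities (the isoactivity condition). The miscibility gap is detected
#' on a composition scan of the reduced mixing Gibbs energy; the tie-line is
#' then refined either by a damped Newton solve of the 2x2 isoactivity
#' system (`method = "direct"`) or by the alternating-tangents iteration
#' (`method = "alternating"`), which alternately re-tangents each phase.
#' The trivial root is rejected.
#'
#' @param components List of two [component()]s.
#' @param config A [model_config()].
#' @param T Temperature in K.
#' @param method `"direct"` or `"alternating"`.
#' @param guess Optional starting tie-line `c(x1_L1, x1_L2)` (e.g. from a
#'   neighboring temperature during continuation).
#' @param n_scan Scan resolution for gap detection.
#' @param tol Convergence tolerance on the isoactivity residual.
#' @return `c(x_L1, x_L2)` with `x_L1 < x_L2` (API mole fractions) and
#'   attribute `residual`, or `NULL` when no phase split exists.
#' @export
solve_lle <- function(components, config, T,
                      method = c("direct", "alternating"),
                      guess = NULL, n_scan = 200L, tol = 1e-10) {
  method <- match.arg(method)
  check_binary(components, c(0.5, 0.5))
  stopifnot(T > 0)
  ws <- residual_workspace(components, T, config)
  eps <- 1e-9

  if (is.null(guess)) {
    xs <- seq(eps, 1 - eps, length.out = n_scan)
    gs <- vapply(xs, function(x) gmix_ws(ws, components, x, config),
                 numeric(1))
    brs <- gap_brackets(xs, gs)
    if (length(brs) == 0L) return(NULL)
    if (length(brs) > 1L) {
      widths <- vapply(brs, diff, numeric(1))
      warning("multiple miscibility gaps detected; solving the widest",
              call. = FALSE)
      brs <- brs[order(widths, decreasing = TRUE)]
    }
    guess <- brs[[1L]]
  }

  out <- switch(method,
    direct = lle_direct(ws, components, config, guess, tol),
    alternating = lle_alternating(ws, components, config, guess, tol))
  if (is.null(out)) return(NULL)
  if (abs(out[1] - out[2]) < 1e-6) return(NULL)  # trivial root
  la1 <- lnact_ws(ws, components, out[1], config)
  la2 <- lnact_ws(ws, components, out[2], config)
  structure(sort(out), residual = max(abs(la1 - la2)))
}

lle_direct <- function(ws, components, config, guess, tol,
                       maxit = 100L, h = 1e-7) {
  z <- guess
  eps <- 1e-12
  Ffun <- function(z) {
    lnact_ws(ws, components, z[1], config) -
      lnact_ws(ws, components, z[2], config)
  }
  Fv <- Ffun(z)
  for (it in seq_len(maxit)) {
    if (max(abs(Fv)) < tol) return(z)
    J <- matrix(0, 2L, 2L)
    for (j in 1:2) {
      zp <- z
      zp[j] <- zp[j] + h
      J[, j] <- (Ffun(zp) - Fv) / h
    }
    step <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      zn <- pmin(pmax(z - lambda * step, eps), 1 - eps)
      Fn <- Ffun(zn)
      if (all(is.finite(Fn)) &&
          (max(abs(Fn)) < max(abs(Fv)) || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    z <- zn
    Fv <- Fn
  }
  if (max(abs(Fv)) < tol) return(z)
  stop(sprintf(
    "direct LLE solve failed at T = %.2f K: residuals (%.3e, %.3e) after %d iterations",
    ws$T, Fv[1], Fv[2], maxit), call. = FALSE)
}

lle_alternating <- function(ws, components, config, guess, tol,
                            maxit = 200L) {
  eps <- 1e-9
  g <- function(x) gmix_ws(ws, components, x, config)
  dg <- function(x) dgmix_ws(ws, components, x, config)
  # tangency residual: tangent at x passes through (x_anchor, g(x_anchor))
  tangency <- function(x, xa, ga) dg(x) - (ga - g(x)) / (xa - x)
  refine <- function(lo, hi, xa, ga) {
    f <- function(x) tangency(x, xa, ga)
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-14)$root
  }
  xa <- guess[1]; xb <- guess[2]
  for (it in seq_len(maxit)) {
    mid <- (xa + xb) / 2
    xb_new <- refine(mid, 1 - eps, xa, g(xa))
    if (is.na(xb_new)) xb_new <- xb
    xa_new <- refine(eps, mid, xb_new, g(xb_new))
    if (is.na(xa_new)) xa_new <- xa
    delta <- max(abs(xa_new - xa), abs(xb_new - xb))
    xa <- xa_new; xb <- xb_new
    if (delta < 1e-13) break
  }
  la <- lnact_ws(ws, components, xa, config)
  lb <- lnact_ws(ws, components, xb, config)
  if (max(abs(la - lb)) > sqrt(tol)) {
    stop(sprintf(
      "alternating-tangents LLE solve failed at T = %.2f K: residuals (%.3e, %.3e)",
      ws$T, la[1] - lb[1], la[2] - lb[2]), call. = FALSE)
  }
  c(xa, xb)
}

#' Spinodal compositions at one temperature
#'
#' Roots of \eqn{\partial^2 (\Delta g_{mix}/RT) / \partial x^2 = 0},
#' computed by central differencing of the exact first derivative
#' \eqn{\ln a_1 - \ln a_2}. Returns an empty result when the mixture is
#' locally stable everywhere.
#'
#' @inheritParams solve_lle
#' @return Sorted numeric vector of spinodal API mole fractions (possibly
#'   length 0).
#' @export
spinodal <- function(components, config, T, n_scan = 200L) {
  check_binary(components, c(0.5, 0.5))
  ws <- residual_workspace(components, T, config)
  eps <- 1e-5   # must leave room for the central-difference stencil
  xs <- seq(eps, 1 - eps, length.out = n_scan)
  cv <- vapply(xs, function(x) curvature_ws(ws, components, x, config),
               numeric(1))
  sgn <- sign(cv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  sort(vapply(flips, function(i) {
    stats::uniroot(function(x) curvature_ws(ws, components, x, config),
                   lower = xs[i], upper = xs[i + 1L], tol = 1e-12)$root
  }, numeric(1)))
}

# Bisect the temperature at which the phase split appears/disappears.
bracket_critical <- function(components, config, T_split, T_nosplit,
                             tol = 0.01) {
  has_split <- function(T) {
    !is.null(tryCatch(
      solve_lle(components, config, T),
      error = function(e) NULL, warning = function(w) NULL))
  }
  while (abs(T_split - T_nosplit) > tol) {
    Tm <- (T_split + T_nosplit) / 2
    if (has_split(Tm)) T_split <- Tm else T_nosplit <- Tm
  }
  (T_split + T_nosplit) / 2
}

#' Assemble a drug-polymer phase diagram
#'
#' Computes the SLE solubility curve over a temperature grid, traces the
#' LLE binodal by continuation (previous tie-line as the next starting
#' guess), collects spinodal points, brackets the critical temperatures
#' where the phase split vanishes (UCST at the top of a split interval,
#' LCST at the bottom; closed loops have both), and sets the
#' amorphous-amorphous phase separation (AAPS) and metastability flags.
#' The binodal is metastable when it lies entirely below the solubility
#' curve, i.e. every tie-line sits in the supersaturated region
#' `w > w_sat(T)`.
#'
#' @inheritParams solve_lle
#' @param T_grid Monotone increasing temperature grid in K.
#' @param trace_spinodal Logical; also collect spinodal points.
#' @param critical_tol Bracketing tolerance for UCST/LCST in K.
#' @return Object of class `phase_diagram` with data frames `sle`
#'   (`T_K`, `x_api`, `w_api`), `binodal` (`T_K`, `x_L1`, `x_L2`, `w_L1`,
#'   `w_L2`), `spinodal`, a `critical` table (`T_K`, `type`), and logical
#'   flags `aaps` and `metastable`.
#' @export
build_phase_diagram <- function(components, config, T_grid,
                                trace_spinodal = TRUE,
                                critical_tol = 0.01) {
  stopifnot(length(T_grid) >= 2L, all(diff(T_grid) > 0))
  api <- components[[1]]
  M <- vapply(components, `[[`, numeric(1), "M")

  # SLE curve
  sle_T <- T_grid[is.finite(api$Tm) & T_grid < api$Tm]
  sle_x <- vapply(sle_T, function(T) {
    tryCatch(as.numeric(suppressWarnings(solve_sle(components, config, T))),
             error = function(e) NA_real_)
  }, numeric(1))
  sle <- data.frame(T_K = sle_T, x_api = sle_x,
                    w_api = x_to_w(sle_x, M[1], M[2]))
  sle <- sle[is.finite(sle$x_api), , drop = FALSE]

  # LLE binodal with continuation in T
  bino <- data.frame(T_K = numeric(), x_L1 = numeric(), x_L2 = numeric())
  spino <- data.frame(T_K = numeric(), x = numeric())
  guess <- NULL
  for (T in T_grid) {
    tie <- tryCatch(
      solve_lle(components, config, T, guess = guess),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tie) && !is.null(guess)) {
      tie <- tryCatch(   # continuation guess failed: rescan from scratch
        solve_lle(components, config, T),
        error = function(e) NULL, warning = function(w) NULL)
    }
    if (!is.null(tie)) {
      bino <- rbind(bino, data.frame(T_K = T, x_L1 = tie[1], x_L2 = tie[2]))
      guess <- as.numeric(tie)
      if (trace_spinodal) {
        sp <- tryCatch(spinodal(components, config, T),
                       error = function(e) numeric(0))
        if (length(sp)) {
          spino <- rbind(spino, data.frame(T_K = T, x = sp))
        }
      }
    } else {
      guess <- NULL
    }
  }

  # critical points at the boundaries of each split interval
  critical <- data.frame(T_K = numeric(), type = character())
  if (nrow(bino)) {
    split_idx <- match(bino$T_K, T_grid)
    runs <- split(split_idx, cumsum(c(1L, diff(split_idx) != 1L)))
    for (run in runs) {
      top <- run[length(run)]
      bot <- run[1L]
      if (top < length(T_grid)) {
        Tc <- bracket_critical(components, config, T_grid[top],
                               T_grid[top + 1L], critical_tol)
        critical <- rbind(critical, data.frame(T_K = Tc, type = "UCST"))
      }
      if (bot > 1L) {
        Tc <- bracket_critical(components, config, T_grid[bot],
                               T_grid[bot - 1L], critical_tol)
        critical <- rbind(critical, data.frame(T_K = Tc, type = "LCST"))
      }
    }
  }

  bino$w_L1 <- x_to_w(bino$x_L1, M[1], M[2])
  bino$w_L2 <- x_to_w(bino$x_L2, M[1], M[2])
  if (nrow(spino)) spino$w <- x_to_w(spino$x, M[1], M[2])

  aaps <- nrow(bino) > 0L
  metastable <- FALSE
  if (aaps && nrow(sle) > 1L) {
    # saturation weight fraction at the binodal temperatures
    w_sat <- stats::approx(sle$T_K, sle$w_api, xout = bino$T_K,
                           rule = 2)$y
    below <- bino$T_K < api$Tm & bino$w_L1 >= w_sat
    no_sat <- bino$T_K < min(sle$T_K)  # solubility negligible there
    metastable <- all(below | no_sat)
  }

  structure(
    list(sle = sle, binodal = bino, spinodal = spino, critical = critical,
         aaps = aaps, metastable = metastable,
         components = vapply(components, `[[`, character(1), "name"),
         config = config, T_grid = T_grid),
    class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %s / %s over %.1f-%.1f K\n",
              x$components[1], x$components[2],
              min(x$T_grid), max(x$T_grid)))
  cat(sprintf("  SLE points: %d;  binodal tie-lines: %d;  AAPS: %s%s\n",
              nrow(x$sle), nrow(x$binodal),
              if (x$aaps) "yes" else "no",
              if (x$aaps && x$metastable) " (metastable)" else ""))
  if (nrow(x$critical)) {
    for (i in seq_len(nrow(x$critical))) {
      cat(sprintf("  %s = %.2f K\n", x$critical$type[i], x$critical$T_K[i]))
    }
  }
  invisible(x)
}
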
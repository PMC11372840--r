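#' Define a mixture component
#'
#' Bundles everything the activity model needs to know about one species:
#' its sigma-profile (with total surface area and cavity volume), molar
#' mass, liquid and hard-core molar volumes for the free-volume term, the
#' dispersion energy parameter, and — for a crystallizable drug — fusion
#' properties.
#'
#' @param name Species name.
#' @param profile A [sigma_profile()].
#' @param M Molar mass in g/mol.
#' @param v Liquid molar volume at 298 K in cm^3/mol (free-volume term).
#' @param v_hc Hard-core (van der Waals) molar volume in cm^3/mol; must be
#'   smaller than `v`. See [hardcore_volume()].
#' @param eps Dispersion energy parameter \eqn{\epsilon/k_B} in K.
#' @param dispersion_class Molecule class for the dispersion sign rule: one
#'   of `"nhb"`, `"hb-donor-acceptor"`, `"hb-acceptor"`, `"water"`, `"cooh"`.
#' @param Tm Melting point in K (crystallizable API only).
#' @param dHfus Molar enthalpy of fusion at `Tm` in kJ/mol.
#' @param dCp_a,dCp_b Fusion heat-capacity difference as
#'   `dCp_a + dCp_b * T` in J/(K mol).
#' @return Object of class `cosmo_component`.
#' @export
component <- function(name, profile, M, v = NA_real_, v_hc = NA_real_,
                      eps = NA_real_, dispersion_class = "nhb",
                      Tm = NA_real_, dHfus = NA_real_,
                      dCp_a = 0, dCp_b = 0) {
  stopifnot(inherits(profile, "sigma_profile"), M > 0)
  classes <- c("nhb", "hb-donor-acceptor", "hb-acceptor", "water", "cooh")
  if (!dispersion_class %in% classes) {
    stop("dispersion_class must be one of: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  if (is.finite(v) && is.finite(v_hc) && v_hc >= v) {
    stop("hard-core volume must satisfy 0 < v_hc < v (", name, ")",
         call. = FALSE)
  }
  structure(
    list(name = name, profile = profile, M = M, v = v, v_hc = v_hc,
         eps = eps, dispersion_class = dispersion_class,
         Tm = Tm, dHfus = dHfus, dCp_a = dCp_a, dCp_b = dCp_b),
    class = "cosmo_component")
}

#' @export
print.cosmo_component <- function(x, ...) {
  cat(sprintf("<cosmo_component> %s: M = %g g/mol, A = %.1f A^2, V = %.1f A^3",
              x$name, x$M, x$profile$area, x$profile$volume))
  if (is.finite(x$Tm)) cat(sprintf(", Tm = %.2f K", x$Tm))
  cat("\n")
  invisible(x)
}

#' Model configuration
#'
#' Selects one of the six COSMO-SAC configurations (residual term always on;
#' combinatorial term none/SG/FV; dispersion term on/off) together with the
#' numerical settings of the segment fixed-point iteration.
#'
#' @param combinatorial One of `"none"`, `"sg"`, `"fv"`.
#' @param dispersion Logical; include the Margules dispersion term.
#' @param dispersion_A Optional override of the Margules constant: a number,
#'   or a function of temperature `A(T)`. `NULL` computes it from the
#'   components' `eps` parameters.
#' @param param_set Universal parameter set identifier (see
#'   [cosmosac_params()]).
#' @param gamma_tol Convergence tolerance of the segment-activity iteration.
#' @param gamma_maxit Maximum iterations.
#' @param gamma_damp Successive-substitution damping in `(0, 1]` (fraction
#'   of the new iterate).
#' @param diff_step Step for numerical composition derivatives.
#' @return Object of class `cosmo_config`.
#' @seealso [config_from_name()] for the conventional CS / CS_dsp^FV labels.
#' @export
model_config <- function(combinatorial = c("fv", "sg", "none"),
                         dispersion = TRUE, dispersion_A = NULL,
                         param_set = "2010", gamma_tol = 1e-8,
                         gamma_maxit = 500L, gamma_damp = 0.5,
                         diff_step = 1e-5) {
  combinatorial <- match.arg(combinatorial)
  stopifnot(gamma_tol > 0, gamma_maxit >= 1, gamma_damp > 0, gamma_damp <= 1)
  structure(
    list(combinatorial = combinatorial, dispersion = isTRUE(dispersion),
         dispersion_A = dispersion_A, param_set = param_set,
         gamma_tol = gamma_tol, gamma_maxit = as.integer(gamma_maxit),
         gamma_damp = gamma_damp, diff_step = diff_step),
    class = "cosmo_config")
}

#' @rdname model_config
#' @param name Conventional configuration label: one of `"CS"`, `"CS-SG"`,
#'   `"CS-FV"`, `"CS-dsp"`, `"CS-dsp-SG"`, `"CS-dsp-FV"`.
#' @param ... Passed on to [model_config()].
#' @export
config_from_name <- function(name, ...) {
  table <- list(
    "CS"        = list(combinatorial = "none", dispersion = FALSE),
    "CS-SG"     = list(combinatorial = "sg",   dispersion = FALSE),
    "CS-FV"     = list(combinatorial = "fv",   dispersion = FALSE),
    "CS-dsp"    = list(combinatorial = "none", dispersion = TRUE),
    "CS-dsp-SG" = list(combinatorial = "sg",   dispersion = TRUE),
    "CS-dsp-FV" = list(combinatorial = "fv",   dispersion = TRUE))
  if (!name %in% names(table)) {
    stop("unknown configuration '", name, "'; available: ",
         paste(names(table), collapse = ", "), call. = FALSE)
  }
  do.call(model_config, c(table[[name]], list(...)))
}

# ---- residual (segment interaction) term -----------------------------------

# Normalized 153-vector (3 classes x 51 bins, class-major) of a profile.
profile_pvec <- function(profile) {
  as.vector(profile$values) / profile$area
}

# exp(-dW/RT) kernel over all class/bin pairs at temperature T.
# dW(s_m, s_n) = c_ES (s_m + s_n)^2 - c_hb(class_m, class_n) (s_m - s_n)^2,
# with c_hb active only for OH/OT pairs of opposite sign.
exchange_kernel <- function(T, pars) {
  grid <- sigma_grid()
  sig <- rep(grid, times = 3L)
  cls <- rep(1:3, each = 51L)               # 1 = nhb, 2 = oh, 3 = ot
  c_es <- pars$A_ES + pars$B_ES / T^2
  splus <- outer(sig, sig, "+")
  sminus <- outer(sig, sig, "-")
  chb_class <- matrix(0, 3L, 3L)
  chb_class[2L, 2L] <- pars$c_hb_ohoh
  chb_class[3L, 3L] <- pars$c_hb_otot
  chb_class[2L, 3L] <- chb_class[3L, 2L] <- pars$c_hb_ohot
  chb <- chb_class[cls, cls]
  opposite <- outer(sig, sig) < 0
  dW <- c_es * splus^2 - chb * opposite * sminus^2
  exp(-dW / (pars$R_kcal * T))
}

# Damped successive substitution for the segment activity coefficients:
# Gamma(m) = 1 / sum_n p(n) Gamma(n) K(m, n).
solve_segment_gamma <- function(pvec, K, config) {
  gam <- rep(1, length(pvec))
  pg <- pvec * gam
  for (it in seq_len(config$gamma_maxit)) {
    gnew <- 1 / as.vector(K %*% (pvec * gam))
    resid <- max(abs(gnew / gam - 1))
    gam <- config$gamma_damp * gnew + (1 - config$gamma_damp) * gam
    if (resid < config$gamma_tol) {
      return(list(gamma = gam, iterations = it, residual = resid))
    }
  }
  stop(sprintf(
    "segment-activity iteration did not converge in %d steps (residual %.3e)",
    config$gamma_maxit, resid), call. = FALSE)
}

# Precompute everything composition-independent at temperature T.
residual_workspace <- function(components, T, config = model_config()) {
  pars <- cosmosac_params(config$param_set)
  K <- exchange_kernel(T, pars)
  p <- lapply(components, function(cm) profile_pvec(cm$profile))
  A <- vapply(components, function(cm) cm$profile$area, numeric(1))
  ln_gamma_pure <- lapply(p, function(pi) {
    log(solve_segment_gamma(pi, K, config)$gamma)
  })
  list(K = K, p = p, A = A, ln_gamma_pure = ln_gamma_pure,
       a_eff = pars$a_eff, config = config, T = T)
}

# Residual ln(gamma) at mole fractions x given a workspace.
lngamma_residual_ws <- function(ws, x) {
  xa <- x * ws$A
  p_mix <- Reduce(`+`, Map(`*`, ws$p, xa)) / sum(xa)
  sol <- solve_segment_gamma(p_mix, ws$K, ws$config)
  ln_gs <- log(sol$gamma)
  out <- vapply(seq_along(ws$p), function(i) {
    (ws$A[i] / ws$a_eff) * sum(ws$p[[i]] * (ln_gs - ws$ln_gamma_pure[[i]]))
  }, numeric(1))
  attr(out, "iterations") <- sol$iterations
  out
}

#' Residual contribution to ln(gamma)
#'
#' Electrostatic misfit plus hydrogen-bond segment interactions, evaluated
#' from the three-class sigma-profiles by the self-consistent segment
#' activity coefficients of the mixture and of each pure component.
#'
#' @param components List of two [component()]s.
#' @param x Mole fractions (length 2, summing to 1).
#' @param T Temperature in K.
#' @param config A [model_config()].
#' @return Numeric vector of per-component residual ln(gamma); attribute
#'   `iterations` carries the mixture iteration count.
#' @export
lngamma_residual <- function(components, x, T, config = model_config()) {
  check_binary(components, x)
  stopifnot(T > 0)
  ws <- residual_workspace(components, T, config)
  lngamma_residual_ws(ws, x)
}

check_binary <- function(components, x) {
  if (length(components) != 2L || length(x) != 2L) {
    stop("a binary mixture (2 components, 2 mole fractions) is required",
         call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-10 || any(x < 0)) {
    stop("mole fractions must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

# ---- combinatorial terms ----------------------------------------------------

#' Staverman-Guggenheim combinatorial contribution
#'
#' Size/shape entropic term from the normalized cavity volumes
#' `r_i = V_i / r0` and areas `q_i = A_i / q0` (polymers use their
#' replicated values):
#' \deqn{\ln\gamma_i^{SG} = \ln\frac{\phi_i}{x_i}
#'   + \frac{z}{2} q_i \ln\frac{\theta_i}{\phi_i}
#'   + l_i - \frac{\phi_i}{x_i}\sum_j x_j l_j}
#' with \eqn{l_i = \frac{z}{2}(r_i - q_i) - (r_i - 1)} and `z = 10`.
#'
#' @inheritParams lngamma_residual
#' @return Per-component ln(gamma) vector.
#' @export
lngamma_sg <- function(components, x, config = model_config()) {
  check_binary(components, x)
  pars <- cosmosac_params(config$param_set)
  r <- vapply(components, function(cm) cm$profile$volume, numeric(1)) / pars$r0
  q <- vapply(components, function(cm) cm$profile$area, numeric(1)) / pars$q0
  if (anyNA(r) || anyNA(q)) {
    stop("SG term needs cavity area and volume for both components",
         call. = FALSE)
  }
  l <- pars$z / 2 * (r - q) - (r - 1)
  # phi_i / x_i and theta_i / phi_i are composition ratios that stay finite
  # as x_i -> 0, so evaluate them ratio-wise
  phi_over_x <- r / sum(x * r)
  theta_over_phi <- (q / r) * sum(x * r) / sum(x * q)
  log(phi_over_x) + pars$z / 2 * q * log(theta_over_phi) + l -
    phi_over_x * sum(x * l)
}

#' Free-volume combinatorial contribution
#'
#' Flory-Huggins-type term with the volume fraction replaced by the
#' free-volume fraction
#' \eqn{\varphi_i^{FV} = x_i v_i^F / \sum_j x_j v_j^F}, where
#' \eqn{v_i^F = v_i - v_i^{HC}} is the free molar volume (liquid minus
#' hard-core):
#' \deqn{\ln\gamma_i^{FV} = \ln\frac{\varphi_i^{FV}}{x_i}
#'   + 1 - \frac{\varphi_i^{FV}}{x_i}}
#'
#' @inheritParams lngamma_residual
#' @return Per-component ln(gamma) vector.
#' @export
lngamma_fv <- function(components, x) {
  check_binary(components, x)
  v <- vapply(components, `[[`, numeric(1), "v")
  vhc <- vapply(components, `[[`, numeric(1), "v_hc")
  if (anyNA(v) || anyNA(vhc)) {
    stop("FV term needs v and v_hc for both components", call. = FALSE)
  }
  vf <- v - vhc
  if (any(vf <= 0)) {
    stop("free volume v - v_hc must be positive for both components",
         call. = FALSE)
  }
  phi_over_x <- vf / sum(x * vf)
  log(phi_over_x) + 1 - phi_over_x
}

# ---- dispersion term --------------------------------------------------------

# Atomic dispersion parameters eps/kB [K] of the dsp variant, by atom type.
DISPERSION_EPS <- c(
  "C(sp3)" = 115.7023, "C(sp2)" = 117.4650, "C(sp)" = 66.0691,
  "-O-" = 95.6184, "=O" = -11.0549,
  "N(sp3)" = 15.4901, "N(sp2)" = 84.6268, "N(sp)" = 109.6621,
  "F" = 52.9318, "Cl" = 104.2534,
  "H(OH)" = 19.3477, "H(NH)" = 141.1709, "H(H2O)" = 58.3301,
  "H(other)" = 0)

#' Molecular dispersion parameter from atomic contributions
#'
#' Atom-count-weighted mean of the published atomic dispersion parameters.
#' Plain carbon-bound hydrogens (`"H(other)"`) contribute zero but are
#' counted in the atom total.
#'
#' @param type_counts Named integer vector of atom-type counts; names must
#'   be among `names(cosmoscreen:::DISPERSION_EPS)`.
#' @return \eqn{\epsilon/k_B} in K.
#' @export
dispersion_epsilon <- function(type_counts) {
  unknown <- setdiff(names(type_counts), names(DISPERSION_EPS))
  if (length(unknown)) {
    stop("unknown atom types: ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(DISPERSION_EPS), collapse = ", "),
         call. = FALSE)
  }
  if (sum(type_counts) == 0) return(NA_real_)
  sum(type_counts * DISPERSION_EPS[names(type_counts)]) / sum(type_counts)
}

# Margules constant from the components' eps parameters:
# A = w [ (e1 + e2)/2 - sqrt(e1 e2) ], w = +-0.27027 by molecule-class rule.
margules_constant <- function(components, pars) {
  e <- vapply(components, `[[`, numeric(1), "eps")
  if (anyNA(e)) {
    stop("dispersion term needs eps for both components (or a ",
         "dispersion_A override in the configuration)", call. = FALSE)
  }
  cl <- sort(vapply(components, `[[`, character(1), "dispersion_class"))
  neg_pairs <- list(c("hb-acceptor", "water"), c("cooh", "nhb"),
                    c("cooh", "hb-donor-acceptor"), c("cooh", "water"))
  w <- if (any(vapply(neg_pairs, function(p) identical(cl, p), logical(1)))) {
    -pars$w_dsp
  } else {
    pars$w_dsp
  }
  w * (0.5 * (e[1] + e[2]) - sqrt(e[1] * e[2]))
}

#' Dispersion contribution to ln(gamma)
#'
#' Single-constant Margules form for a binary mixture:
#' \eqn{\ln\gamma_1^{dsp} = A x_2^2}, \eqn{\ln\gamma_2^{dsp} = A x_1^2}.
#' The constant `A` comes from the components' atomic dispersion parameters
#' through the arithmetic-minus-geometric-mean combining rule with the
#' molecule-class sign exceptions, unless overridden in the configuration.
#'
#' @inheritParams lngamma_residual
#' @param T Temperature in K; only used when `config$dispersion_A` is a
#'   function of temperature.
#' @return Per-component ln(gamma) vector.
#' @export
lngamma_dsp <- function(components, x, T = NA_real_,
                        config = model_config()) {
  check_binary(components, x)
  A <- dispersion_A_value(components, T, config)
  c(A * x[2]^2, A * x[1]^2)
}

dispersion_A_value <- function(components, T, config) {
  ov <- config$dispersion_A
  if (is.null(ov)) {
    return(margules_constant(components, cosmosac_params(config$param_set)))
  }
  if (is.function(ov)) {
    if (!is.finite(T)) stop("dispersion_A(T) needs a temperature", call. = FALSE)
    return(ov(T))
  }
  as.numeric(ov)
}

# ---- total ------------------------------------------------------------------

#' Total activity coefficient of a binary mixture
#'
#' Sums the residual term with whichever combinatorial (SG or FV) and
#' dispersion terms the configuration activates; inactive terms are reported
#' as exact zeros. The total is the exact sum of the reported parts.
#'
#' @inheritParams lngamma_residual
#' @return Object of class `activity_result`: a list with per-component
#'   vectors `residual`, `combinatorial`, `dispersion`, `total` and the
#'   segment-iteration count `iterations`.
#' @export
lngamma_total <- function(components, x, T, config = model_config()) {
  check_binary(components, x)
  res <- lngamma_residual(components, x, T, config)
  comb <- switch(config$combinatorial,
    none = c(0, 0),
    sg = lngamma_sg(components, x, config),
    fv = lngamma_fv(components, x))
  dsp <- if (config$dispersion) {
    lngamma_dsp(components, x, T, config)
  } else {
    c(0, 0)
  }
  structure(
    list(residual = as.numeric(res), combinatorial = comb, dispersion = dsp,
         total = as.numeric(res) + comb + dsp,
         iterations = attr(res, "iterations")),
    class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  m <- rbind(residual = x$residual, combinatorial = x$combinatorial,
             dispersion = x$dispersion, total = x$total)
  colnames(m) <- c("component 1", "component 2")
  cat("<activity_result> ln(gamma) terms\n")
  print(round(m, 6))
  invisible(x)
}

# ---- hard-core volume -------------------------------------------------------

# Bondi-based atomic van der Waals volume increments [cm^3/mol] (fast
# group-additivity scheme with bond and ring corrections).
ZHAO_ATOM_VOLUMES <- c(
  H = 7.24, C = 20.58, N = 15.60, O = 14.71, F = 13.31, Cl = 22.45,
  Br = 26.52, I = 32.52, P = 24.43, S = 24.43, As = 26.52, B = 40.48,
  Si = 38.79, Se = 28.73, Te = 36.62)

#' Hard-core (van der Waals) molar volume from atom counts
#'
#' Fast Bondi-radius-based estimate:
#' \deqn{v^{HC} = \sum_{el} n_{el} V_{el} - 5.92 N_B - 14.7 R_A - 3.8 R_{NA}}
#' with `N_B` the number of bonds, `R_A` the aromatic and `R_NA` the
#' non-aromatic ring counts, in cm^3/mol.
#'
#' @param atom_counts Named integer vector of element counts (e.g.
#'   `c(C = 6, H = 6)`).
#' @param n_bonds Total number of bonds.
#' @param aromatic_rings,nonaromatic_rings Ring counts.
#' @return Hard-core molar volume in cm^3/mol.
#' @examples
#' hardcore_volume(c(C = 6, H = 6), n_bonds = 12, aromatic_rings = 1) # benzene
#' @export
hardcore_volume <- function(atom_counts, n_bonds = 0, aromatic_rings = 0,
                            nonaromatic_rings = 0) {
  stopifnot(all(atom_counts >= 0), n_bonds >= 0,
            aromatic_rings >= 0, nonaromatic_rings >= 0)
  if (length(atom_counts) == 0L || sum(atom_counts) == 0) return(0)
  unknown <- setdiff(names(atom_counts), names(ZHAO_ATOM_VOLUMES))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(ZHAO_ATOM_VOLUMES), collapse = ", "),
         call. = FALSE)
  }
  sum(atom_counts * ZHAO_ATOM_VOLUMES[names(atom_counts)]) -
    5.92 * n_bonds - 14.7 * aromatic_rings - 3.8 * nonaromatic_rings
}
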
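# Deterministic fixtures: synthetic cavities, analytic binary systems, and
# packaged API fusion constants. Everything is generated in code; nothing is
# downloaded.

# Run fn with a private RNG state seeded by `seed`.
with_fixture_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

# Deterministic quasi-uniform points on a unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

#' Generate a synthetic COSMO segment set
#'
#' Builds a random but structurally valid closed cavity: segments on a
#' sphere of radius `radius` (areas positive, summing exactly to the header
#' area), atoms grouped into `n_units` contiguous monomer units along the
#' cavity axis, and per-unit screening-charge offsets so units are
#' distinguishable. Segment ownership follows the nearest atom. The same
#' seed reproduces the fixture bit-identically.
#'
#' @param n_segments Number of surface segments.
#' @param n_units Number of monomer units the atoms partition into.
#' @param atoms_per_unit Atoms per unit.
#' @param sigma_offsets Per-unit mean screening charge density in e/A^2
#'   (recycled); default 0 for all units.
#' @param sigma_sd Standard deviation of the segment charge noise.
#' @param radius Cavity radius in Angstrom.
#' @param seed Integer seed.
#' @param name Molecule name.
#' @return A [segment_set()] (raw, unaveraged) with attribute `unit_atoms`,
#'   a list of atom-index vectors per unit.
#' @export
gen_segment_set <- function(n_segments = 120L, n_units = 1L,
                            atoms_per_unit = 3L, sigma_offsets = 0,
                            sigma_sd = 0.003, radius = 4, seed = 1L,
                            name = sprintf("fixture-%d", seed)) {
  stopifnot(n_segments >= n_units, n_units >= 1L, atoms_per_unit >= 1L)
  sigma_offsets <- rep_len(sigma_offsets, n_units)
  with_fixture_seed(seed, function() {
    n_atoms <- n_units * atoms_per_unit
    # atoms stacked unit-by-unit along z inside the cavity
    az <- seq(-0.6, 0.6, length.out = n_atoms) * radius
    atoms <- data.frame(
      element = rep(c("c", "o", "h"), length.out = n_atoms),
      x = stats::runif(n_atoms, -0.2, 0.2) * radius,
      y = stats::runif(n_atoms, -0.2, 0.2) * radius,
      z = az, stringsAsFactors = FALSE)
    unit_atoms <- split(seq_len(n_atoms),
                        rep(seq_len(n_units), each = atoms_per_unit))

    pos <- fibonacci_sphere(n_segments) * radius
    area_total <- 4 * pi * radius^2
    areas <- stats::runif(n_segments, 0.5, 1.5)
    areas <- areas * (area_total / sum(areas))
    # owning atom = nearest atom
    d2 <- outer(pos[, 1], atoms$x, "-")^2 +
      outer(pos[, 2], atoms$y, "-")^2 + outer(pos[, 3], atoms$z, "-")^2
    owner <- max.col(-d2, ties.method = "first")
    unit_of_atom <- rep(seq_len(n_units), each = atoms_per_unit)
    sig <- sigma_offsets[unit_of_atom[owner]] +
      stats::rnorm(n_segments, 0, sigma_sd)
    sig <- pmin(pmax(sig, -0.02), 0.02)
    segments <- data.frame(atom = owner, x = pos[, 1], y = pos[, 2],
                           z = pos[, 3], area = areas, sigma = sig)
    out <- segment_set(name, atoms, segments, area = area_total,
                       volume = 4 / 3 * pi * radius^3, averaged = FALSE)
    attr(out, "unit_atoms") <- unit_atoms
    out
  })
}

#' Analytic binary system with a prescribed Margules constant
#'
#' Constructs two components sharing one sigma-profile (residual term
#' identically zero), with equal Staverman-Guggenheim parameters and equal
#' free volumes (both combinatorial terms identically zero), and dispersion
#' parameters chosen in closed form so the Margules combining rule
#' reproduces exactly the requested constant `A`. The total ln(gamma) of any
#' configuration therefore reduces to the pure Margules form
#' \eqn{\ln\gamma_1 = A x_2^2}, which has known closed-form phase behavior
#' (symmetric critical point at `A = 2`, `x = 1/2`).
#'
#' @param A Margules constant (must be `>= 0` for the closed-form epsilon
#'   construction).
#' @param M Molar masses of the two components in g/mol.
#' @param Tm,dHfus,dCp_a,dCp_b Fusion properties attached to component 1 so
#'   it can act as the crystallizable API.
#' @return List of two [component()]s.
#' @export
gen_analytic_system <- function(A, M = c(230, 25000), Tm = 450,
                                dHfus = 30, dCp_a = 0, dCp_b = 0) {
  stopifnot(A >= 0)
  pars <- cosmosac_params()
  # single smooth NHB hump on the grid, identical for both components
  g <- sigma_grid()
  hump <- exp(-g^2 / (2 * 0.005^2))
  vals <- cbind(nhb = 200 * hump / sum(hump), oh = 0, ot = 0)
  prof <- sigma_profile(vals, volume = 250, name = "analytic")
  # invert A = w [ (e1+e2)/2 - sqrt(e1 e2) ] = w (sqrt(e1) - sqrt(e2))^2 / 2
  s2 <- 10                               # sqrt(eps_2), eps_2 = 100 K
  s1 <- s2 + sqrt(2 * A / pars$w_dsp)
  list(
    component("analytic-api", prof, M = M[1], v = 160, v_hc = 100,
              eps = s1^2, Tm = Tm, dHfus = dHfus,
              dCp_a = dCp_a, dCp_b = dCp_b),
    component("analytic-poly", prof, M = M[2], v = 1060, v_hc = 1000,
              eps = s2^2))
}

#' Fusion properties of the seven reference drugs
#'
#' Packaged melting-point, enthalpy-of-fusion and fusion heat-capacity
#' constants of griseofulvin (GSF), ibuprofen (IBP), indomethacin (IMC),
#' nifedipine (NIF), naproxen (NPX), paracetamol (PCM) and simvastatin
#' (SIM). The heat-capacity difference is linear in temperature,
#' `dCp_a + dCp_b * T` in J/(K mol).
#'
#' @return data.frame with columns `api`, `Tm`, `dHfus`, `dCp_a`, `dCp_b`.
#' @export
table1_api <- function() {
  data.frame(
    api = c("GSF", "IBP", "IMC", "NIF", "NPX", "PCM", "SIM"),
    Tm = c(491.85, 348.55, 433.35, 445.75, 429.25, 442.55, 412.45),
    dHfus = c(37.90, 26.40, 38.10, 39.30, 32.40, 28.00, 27.75),
    dCp_a = c(93.84, 176.16440, 238.18385, 121.22, 99.30, 99.80, 278.77100),
    dCp_b = c(0, -0.3449480, -0.2785901, 0, 0, 0, -0.331300),
    stringsAsFactors = FALSE)
}

#' Build API components from the packaged fusion table
#'
#' Convenience wrapper attaching the [table1_api()] constants to dummy
#' profiles so fusion-property code paths can be exercised without QM data.
#'
#' @param apis Character vector of API codes (default: all seven).
#' @return Named list of [component()]s.
#' @export
table1_components <- function(apis = table1_api()$api) {
  tab <- table1_api()
  g <- sigma_grid()
  hump <- exp(-g^2 / (2 * 0.004^2))
  prof <- sigma_profile(cbind(300 * hump / sum(hump), 0, 0),
                        volume = 300, name = "api-dummy")
  out <- lapply(apis, function(a) {
    row <- tab[tab$api == a, ]
    if (nrow(row) != 1L) stop("unknown API code: ", a, call. = FALSE)
    component(a, prof, M = 300, v = 250, v_hc = 160, eps = 100,
              Tm = row$Tm, dHfus = row$dHfus,
              dCp_a = row$dCp_a, dCp_b = row$dCp_b)
  })
  names(out) <- apis
  out
}
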
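test_that("residual term vanishes for pure components and identical profiles", {
  sys <- random_system(101L)
  cfg <- tight_config()
  expect_equal(as.numeric(lngamma_residual(sys, c(1, 0), 300, cfg))[1], 0)
  expect_equal(as.numeric(lngamma_residual(sys, c(0, 1), 300, cfg))[2], 0)
  # identical sigma-profiles and areas: zero for both at any composition
  twin <- list(sys[[1]], sys[[1]])
  for (x1 in c(0.2, 0.5, 0.9)) {
    expect_equal(as.numeric(lngamma_residual(twin, c(x1, 1 - x1), 310, cfg)),
                 c(0, 0))
  }
})

test_that("residual term matches the independent fixed-point oracle", {
  # sparse 3-bin profiles spanning all classes, with HB-active charges
  p1 <- sparse_profile(bins = c(16, 26, 36), areas = c(30, 40, 30),
                       classes = c("oh", "nhb", "oh"), name = "a")
  p2 <- sparse_profile(bins = c(12, 26, 40), areas = c(25, 60, 25),
                       classes = c("ot", "nhb", "ot"), name = "b")
  sys <- list(component("a", p1, M = 100), component("b", p2, M = 200))
  cfg <- tight_config()
  for (case in list(list(x = c(0.5, 0.5), T = 298.15),
                    list(x = c(0.2, 0.8), T = 350))) {
    got <- as.numeric(lngamma_residual(sys, case$x, case$T, cfg))
    want <- oracle_residual(list(p1, p2), case$x, case$T)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("three-class residual reduces to single-class when OH/OT are empty", {
  p_three <- sparse_profile(bins = c(20, 26, 32), areas = c(20, 50, 30),
                            classes = "nhb")
  sys <- list(component("a", p_three, M = 100),
              component("b", sparse_profile(24, 100, "nhb"), M = 150))
  got <- as.numeric(lngamma_residual(sys, c(0.4, 0.6), 320, tight_config()))
  # single-class oracle: collapse classes before solving
  collapse <- function(p) sigma_profile(cbind(rowSums(p$values), 0, 0),
                                        p$volume, p$name)
  want <- oracle_residual(lapply(list(sys[[1]]$profile, sys[[2]]$profile),
                                 collapse), c(0.4, 0.6), 320)
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("SG term matches direct formula arithmetic and its limits", {
  sys <- random_system(7L)
  # pure-component limit
  expect_equal(lngamma_sg(sys, c(1, 0))[1], 0)
  expect_equal(lngamma_sg(sys, c(0, 1))[2], 0)
  # equal normalized area and volume: zero at all x
  twin <- list(sys[[1]], sys[[1]])
  expect_equal(lngamma_sg(twin, c(0.3, 0.7)), c(0, 0))

  # hand evaluation for a toy (r, q) pair at x = 0.3
  pars <- cosmosac_params()
  A <- c(120, 480); V <- c(100, 500)
  p1 <- sparse_profile(26, A[1], volume = V[1])
  p2 <- sparse_profile(26, A[2], volume = V[2])
  toy <- list(component("a", p1, M = 1), component("b", p2, M = 1))
  x <- c(0.3, 0.7)
  r <- V / pars$r0; q <- A / pars$q0
  l <- pars$z / 2 * (r - q) - (r - 1)
  phi <- x * r / sum(x * r); theta <- x * q / sum(x * q)
  want <- log(phi / x) + pars$z / 2 * q * log(theta / phi) + l -
    phi / x * sum(x * l)
  expect_equal(lngamma_sg(toy, x), want, tolerance = 1e-12)
})

test_that("FV term follows the free-volume fractions", {
  mkc <- function(v, vhc) {
    component("c", sparse_profile(26, 100), M = 100, v = v, v_hc = vhc)
  }
  # equal free volumes: ideal at all compositions
  sysq <- list(mkc(160, 100), mkc(1060, 1000))
  expect_equal(lngamma_fv(sysq, c(0.37, 0.63)), c(0, 0))
  # pure limit
  sys <- list(mkc(100, 50), mkc(6000, 1000))
  expect_equal(lngamma_fv(sys, c(1, 0))[1], 0)
  # hand evaluation: v_F = (50, 5000), x = (0.5, 0.5)
  phi <- c(50, 5000) / (0.5 * 50 + 0.5 * 5000) * 0.5
  want <- log(phi / 0.5) + 1 - phi / 0.5
  expect_equal(lngamma_fv(sys, c(0.5, 0.5)), want, tolerance = 1e-12)
  # invariant breach
  expect_error(component("bad", sparse_profile(26, 10), M = 1,
                         v = 50, v_hc = 60), "v_hc < v")
})

test_that("dispersion term is a single-constant Margules form", {
  mkc <- function(eps, cls = "nhb") {
    component("c", sparse_profile(26, 100), M = 100, eps = eps,
              dispersion_class = cls)
  }
  cfg <- model_config()
  # x2 = 0 gives zero for component 1; equal eps gives A = 0
  expect_equal(lngamma_dsp(list(mkc(100), mkc(80)), c(1, 0))[1], 0)
  expect_equal(lngamma_dsp(list(mkc(90), mkc(90)), c(0.3, 0.7)), c(0, 0))
  # A = 0.8 override: ln gamma = (0.45, 0.05) at x = (0.25, 0.75)
  cfgA <- model_config(dispersion_A = 0.8)
  expect_equal(lngamma_dsp(list(mkc(1), mkc(2)), c(0.25, 0.75),
                           config = cfgA), c(0.45, 0.05))
  # combining rule: w [ (e1+e2)/2 - sqrt(e1 e2) ]
  got <- lngamma_dsp(list(mkc(150), mkc(60)), c(0.4, 0.6), 300)
  A <- 0.27027 * (0.5 * (150 + 60) - sqrt(150 * 60))
  expect_equal(got, c(A * 0.36, A * 0.16), tolerance = 1e-12)
  # sign-exception class pair flips w
  got2 <- lngamma_dsp(list(mkc(150, "water"), mkc(60, "hb-acceptor")),
                      c(0.4, 0.6), 300)
  expect_equal(got2, -got, tolerance = 1e-12)
  expect_error(lngamma_dsp(list(mkc(NA), mkc(60)), c(0.5, 0.5)), "eps")
})

test_that("total recomposes exactly from its active terms", {
  sys <- random_system(31L)
  x <- c(0.35, 0.65); T <- 330
  cfg_names <- c("CS", "CS-SG", "CS-FV", "CS-dsp", "CS-dsp-SG", "CS-dsp-FV")
  for (nm in cfg_names) {
    cfg <- config_from_name(nm, gamma_tol = 1e-12)
    r <- lngamma_total(sys, x, T, cfg)
    expect_identical(r$total, r$residual + r$combinatorial + r$dispersion)
    if (cfg$combinatorial == "none") expect_identical(r$combinatorial, c(0, 0))
    if (!cfg$dispersion) expect_identical(r$dispersion, c(0, 0))
  }
  # CS: residual only
  r <- lngamma_total(sys, x, T, config_from_name("CS"))
  expect_identical(r$total, r$residual)
  # independently summed sub-terms for CS-dsp-SG
  cfg <- config_from_name("CS-dsp-SG", gamma_tol = 1e-12)
  r <- lngamma_total(sys, x, T, cfg)
  expect_equal(r$total,
               as.numeric(lngamma_residual(sys, x, T, cfg)) +
                 lngamma_sg(sys, x, cfg) + lngamma_dsp(sys, x, T, cfg))
  # identical components: everything zero
  twin <- list(sys[[1]], sys[[1]])
  r0 <- lngamma_total(twin, c(0.4, 0.6), T, config_from_name("CS-dsp-FV"))
  expect_equal(r0$total, c(0, 0))
})

test_that("Gibbs-Duhem holds across configurations and random systems", {
  h <- 1e-5
  for (seed in c(3L, 57L)) {
    sys <- random_system(seed)
    for (nm in c("CS", "CS-dsp-SG", "CS-dsp-FV")) {
      cfg <- config_from_name(nm, gamma_tol = 1e-12, gamma_maxit = 3000L)
      for (x1 in c(0.25, 0.6)) {
        lg_p <- lngamma_total(sys, c(x1 + h, 1 - x1 - h), 310, cfg)$total
        lg_m <- lngamma_total(sys, c(x1 - h, 1 - x1 + h), 310, cfg)$total
        gd <- x1 * (lg_p[1] - lg_m[1]) / (2 * h) +
          (1 - x1) * (lg_p[2] - lg_m[2]) / (2 * h)
        expect_lt(abs(gd), 1e-5)
      }
    }
  }
})

test_that("FV minus Flory-Huggins equals the closed-form difference", {
  # term-by-term difference against the closed form, to 1e-10
  set.seed(4)
  for (rep in 1:20) {
    v <- stats::runif(2, 80, 4000)
    vhc <- v * stats::runif(2, 0.4, 0.9)
    x1 <- stats::runif(1, 0.02, 0.98)
    x <- c(x1, 1 - x1)
    sys <- list(
      component("a", sparse_profile(26, 100), M = 1, v = v[1], v_hc = vhc[1]),
      component("b", sparse_profile(26, 100), M = 1, v = v[2], v_hc = vhc[2]))
    fv <- lngamma_fv(sys, x)
    phi <- x * v / sum(x * v)
    fh <- log(phi / x) + 1 - phi / x
    vf <- v - vhc
    phif <- x * vf / sum(x * vf)
    closed <- log(phif / phi) + phi / x - phif / x
    expect_lt(max(abs((fv - fh) - closed)), 1e-10)
  }
})

test_that("hard-core volume follows the atomic increment scheme", {
  expect_equal(hardcore_volume(integer(0)), 0)
  # benzene: 6 C + 6 H, 12 bonds, 1 aromatic ring
  benzene <- hardcore_volume(c(C = 6, H = 6), n_bonds = 12,
                             aromatic_rings = 1)
  expect_equal(benzene, 6 * 20.58 + 6 * 7.24 - 5.92 * 12 - 14.7,
               tolerance = 1e-12)
  # linearity: doubling all counts doubles the result
  expect_equal(hardcore_volume(c(C = 12, H = 12), n_bonds = 24,
                               aromatic_rings = 2), 2 * benzene)
  expect_error(hardcore_volume(c(Xx = 1)), "unknown element")
})

test_that("molecular dispersion parameter averages atomic contributions", {
  # methanol: 1 C(sp3), 1 -O-, 1 H(OH), 3 H(other)
  eps <- dispersion_epsilon(c("C(sp3)" = 1, "-O-" = 1, "H(OH)" = 1,
                              "H(other)" = 3))
  expect_equal(eps, (115.7023 + 95.6184 + 19.3477) / 6, tolerance = 1e-12)
  expect_error(dispersion_epsilon(c(Q = 1)), "unknown atom types")
})

test_that("segment iteration reports non-convergence with its residual", {
  sys <- random_system(5L)
  cfg <- model_config(gamma_maxit = 2L)
  expect_error(lngamma_residual(sys, c(0.5, 0.5), 300, cfg),
               "did not converge")
})
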
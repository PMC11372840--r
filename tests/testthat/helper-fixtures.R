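# Shared fixtures built in code at test time.

# Tight-tolerance configuration for derivative-based property tests.
tight_config <- function(...) {
  model_config(gamma_tol = 1e-12, gamma_maxit = 3000L, ...)
}

# A sigma-profile with all area in chosen (bin, class) slots.
sparse_profile <- function(bins, areas, classes = "nhb", volume = 100,
                           name = "sparse") {
  classes <- rep_len(classes, length(bins))
  vals <- matrix(0, 51, 3, dimnames = list(NULL, c("nhb", "oh", "ot")))
  for (i in seq_along(bins)) {
    vals[bins[i], classes[i]] <- vals[bins[i], classes[i]] + areas[i]
  }
  sigma_profile(vals, volume = volume, name = name)
}

# Random small synthetic component pair for property tests.
random_system <- function(seed, hb = TRUE) {
  seg1 <- gen_segment_set(n_segments = 90L, n_units = 1L, atoms_per_unit = 3L,
                          sigma_offsets = 0.002, seed = seed,
                          name = "rand-a")
  seg2 <- gen_segment_set(n_segments = 110L, n_units = 1L, atoms_per_unit = 3L,
                          sigma_offsets = -0.003, seed = seed + 1000L,
                          radius = 5, name = "rand-b")
  cls1 <- if (hb) c("nhb", "oh", "nhb") else rep("nhb", 3)
  cls2 <- if (hb) c("ot", "nhb", "nhb") else rep("nhb", 3)
  p1 <- build_profile(average_charge_density(seg1), cls1)
  p2 <- build_profile(average_charge_density(seg2), cls2)
  list(component("rand-a", p1, M = 250, v = 200, v_hc = 120, eps = 120),
       component("rand-b", p2, M = 400, v = 350, v_hc = 240, eps = 90))
}
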
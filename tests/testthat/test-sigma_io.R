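test_that("cosmo file round-trips through the fixture writer and parser", {
  seg <- gen_segment_set(n_segments = 80L, n_units = 2L, atoms_per_unit = 2L,
                         sigma_offsets = c(0.002, -0.002), seed = 11L)
  path <- withr::local_tempfile(fileext = ".cosmo")
  write_cosmo(seg, path)
  back <- parse_cosmo(path)
  expect_s3_class(back, "cosmo_segments")
  expect_equal(nrow(back$segments), 80L)
  expect_equal(sum(back$segments$area), back$area, tolerance = 1e-9)
  expect_equal(back$segments$sigma, seg$segments$sigma, tolerance = 1e-9)
  expect_equal(back$atoms$z, seg$atoms$z, tolerance = 1e-9)
  expect_false(back$averaged)
})

test_that("parser rejects degenerate cosmo input", {
  seg <- gen_segment_set(n_segments = 12L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".cosmo")
  write_cosmo(seg, path)
  lines <- readLines(path)
  cut <- grep("^\\$segment_information", lines)
  writeLines(lines[seq_len(cut - 1L)], path)
  expect_error(parse_cosmo(path), "segment_information")
  expect_error(parse_cosmo(tempfile()), "no such file")
  # all-zero charges parse to sigma = 0 everywhere
  seg0 <- seg
  seg0$segments$sigma <- 0
  write_cosmo(seg0, path)
  expect_equal(parse_cosmo(path)$segments$sigma, rep(0, 12L))
})

test_that("segment-set invariants are enforced", {
  seg <- gen_segment_set(n_segments = 20L, seed = 5L)
  bad <- seg$segments
  bad$area[1] <- -1
  expect_error(segment_set("x", seg$atoms, bad, seg$area, seg$volume),
               "positive")
  bad <- seg$segments
  bad$atom[1] <- 99L
  expect_error(segment_set("x", seg$atoms, bad, seg$area, seg$volume),
               "existing atoms")
  expect_error(segment_set("x", seg$atoms, seg$segments,
                           area = 2 * seg$area, volume = seg$volume),
               "0.5%")
})

test_that("charge-density averaging matches a direct hand evaluation", {
  # 3-segment toy set: evaluate the weighting formula scalar-by-scalar
  atoms <- data.frame(element = "c", x = 0, y = 0, z = 0)
  segs <- data.frame(atom = 1L,
                     x = c(0, 1, 2), y = 0, z = 0,
                     area = c(1, 2, 3), sigma = c(0.01, -0.005, 0.002))
  seg <- segment_set("toy", atoms, segs, area = 6, volume = 10)
  out <- average_charge_density(seg, r_av = 0.5, f_decay = 3.57)

  rn2 <- segs$area / pi
  rav2 <- 0.25
  expected <- sapply(1:3, function(m) {
    num <- den <- 0
    for (n in 1:3) {
      d2 <- (segs$x[m] - segs$x[n])^2
      w <- rn2[n] * rav2 / (rn2[n] + rav2) *
        exp(-3.57 * d2 / (rn2[n] + rav2))
      num <- num + segs$sigma[n] * w
      den <- den + w
    }
    num / den
  })
  expect_equal(out$segments$sigma, expected, tolerance = 1e-14)
  expect_equal(out$segments$area, segs$area)  # areas untouched
  expect_true(out$averaged)
})

test_that("averaging is the identity on single-segment and uniform cavities", {
  atoms <- data.frame(element = "c", x = 0, y = 0, z = 0)
  one <- segment_set("one", atoms,
                     data.frame(atom = 1L, x = 0, y = 0, z = 0,
                                area = 5, sigma = 0.01),
                     area = 5, volume = 4)
  expect_equal(average_charge_density(one)$segments$sigma, 0.01)

  seg <- gen_segment_set(n_segments = 60L, seed = 9L)
  seg$segments$sigma <- 0.004
  av <- average_charge_density(seg)
  expect_equal(av$segments$sigma, rep(0.004, 60L), tolerance = 1e-14)
})

test_that("averaging approximately conserves total charge on closed cavities", {
  seg <- gen_segment_set(n_segments = 200L, sigma_offsets = 0.005, seed = 21L)
  av <- average_charge_density(seg)
  q_raw <- sum(seg$segments$sigma * seg$segments$area)
  q_av <- sum(av$segments$sigma * av$segments$area)
  expect_lt(abs(q_av - q_raw), 0.01 * abs(q_raw))
})

test_that("profile binning conserves area and places sigma correctly", {
  # all sigma = 0: everything in the central bin (26), NHB class
  seg <- gen_segment_set(n_segments = 40L, seed = 2L)
  seg$segments$sigma <- 0
  seg$averaged <- TRUE
  prof <- build_profile(seg)
  expect_equal(unname(prof$values[26, "nhb"]), sum(seg$segments$area))
  expect_equal(sum(prof$values), sum(seg$segments$area))

  # sigma exactly on a grid node: single bin
  seg$segments$sigma <- 0.003
  prof <- build_profile(seg)
  expect_equal(unname(prof$values[29, "nhb"]), sum(seg$segments$area))
  expect_equal(sum(prof$values != 0), 1L)

  # two segments between nodes: hand-computed interpolation weights
  atoms <- data.frame(element = "c", x = 0, y = 0, z = 0)
  seg2 <- segment_set("toy", atoms,
                      data.frame(atom = 1L, x = c(0, 1), y = 0, z = 0,
                                 area = c(2, 4),
                                 sigma = c(0.00025, -0.0007)),
                      area = 6, volume = 5, averaged = TRUE)
  prof2 <- build_profile(seg2)
  # 0.00025 -> 75% bin 26 (sigma 0.000), 25% bin 27 (0.001)
  # -0.0007 -> 70% bin 25 (-0.001), 30% bin 26
  expect_equal(unname(prof2$values[26, "nhb"]), 2 * 0.75 + 4 * 0.3)
  expect_equal(unname(prof2$values[27, "nhb"]), 2 * 0.25)
  expect_equal(unname(prof2$values[25, "nhb"]), 4 * 0.7)
  expect_equal(sum(prof2$values), 6)
})

test_that("HB classes use the switching function; near-neutral counts as NHB", {
  atoms <- data.frame(element = c("o", "h"), x = c(0, 1), y = 0, z = 0)
  segs <- data.frame(atom = c(1L, 2L), x = c(0, 1), y = 0, z = 0,
                     area = c(3, 5), sigma = c(0.012, 0))
  seg <- segment_set("hb", atoms, segs, area = 8, volume = 9,
                     averaged = TRUE)
  prof <- build_profile(seg, hb_atom_classes = c("oh", "oh"))
  p_hb <- 1 - exp(-0.012^2 / (2 * 0.007^2))
  expect_equal(sum(prof$values[, "oh"]), 3 * p_hb, tolerance = 1e-12)
  # the sigma = 0 segment has switching weight 0: all NHB
  expect_equal(sum(prof$values[, "nhb"]), 5 + 3 * (1 - p_hb),
               tolerance = 1e-12)
  expect_equal(sum(prof$values), 8)

  # out-of-grid sigma clamps with a warning
  segs$sigma[1] <- 0.05
  seg_bad <- segment_set("hb", atoms, segs, area = 8, volume = 9,
                         averaged = TRUE)
  expect_warning(p <- build_profile(seg_bad, c("nhb", "nhb")), "clamped")
  expect_equal(unname(p$values[51, "nhb"]), 3)
})

test_that("area conservation holds on arbitrary fixtures", {
  for (seed in c(1L, 17L, 33L)) {
    seg <- average_charge_density(
      gen_segment_set(n_segments = 150L, n_units = 3L,
                      sigma_offsets = c(0.006, 0, -0.006), seed = seed))
    cls <- rep(c("oh", "nhb", "ot"), each = 3L)
    prof <- build_profile(seg, cls)
    expect_lt(abs(sum(prof$values) - sum(seg$segments$area)) /
                sum(seg$segments$area), 1e-6)
  }
})

test_that("sigma file format round-trips and validates", {
  seg <- average_charge_density(
    gen_segment_set(n_segments = 100L, n_units = 2L, atoms_per_unit = 2L,
                    sigma_offsets = c(0.005, -0.004), seed = 8L))
  prof <- build_profile(seg, c("oh", "nhb", "ot", "nhb"))
  path <- withr::local_tempfile(fileext = ".sigma")
  write_sigma(prof, path)
  back <- read_sigma(path)
  expect_identical(back$values, prof$values)    # bit-exact round trip
  expect_identical(back$volume, prof$volume)
  expect_identical(back$name, prof$name)

  # single-class legacy variant loads with all area as NHB
  write_sigma(prof, path, classes = "single")
  legacy <- read_sigma(path)
  expect_equal(legacy$values[, "nhb"], rowSums(prof$values))
  expect_equal(legacy$values[, "oh"], rep(0, 51))

  # malformed input
  lines <- readLines(path)
  writeLines(lines[-10L], path)
  expect_error(read_sigma(path), "51 data rows")
  write_sigma(prof, path)
  lines <- readLines(path)
  lines[7] <- sub("^(\\s*\\S+\\s+)\\S+", "\\1not_a_number", lines[7])
  writeLines(lines, path)
  expect_error(read_sigma(path), "data line 3")
})
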
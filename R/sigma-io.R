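#' Construct a COSMO segment set
#'
#' A segment set is the parsed content of a COSMO cavity calculation: the
#' atoms of the molecule and the surface segments of the screening cavity,
#' each with a position, an area and a screening charge density sigma.
#'
#' @param name Molecule name.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (Angstrom).
#' @param segments data.frame with columns `atom` (1-based owning atom
#'   index), `x`, `y`, `z` (Angstrom), `area` (A^2), `sigma` (e/A^2).
#' @param area Total cavity surface area in A^2 (from the COSMO header).
#' @param volume Total cavity volume in A^3.
#' @param averaged Logical; whether `sigma` has already undergone the
#'   distance-weighted averaging step.
#' @return Object of class `cosmo_segments`.
#' @export
segment_set <- function(name, atoms, segments, area, volume,
                        averaged = FALSE) {
  stopifnot(is.data.frame(atoms), is.data.frame(segments))
  need_a <- c("element", "x", "y", "z")
  need_s <- c("atom", "x", "y", "z", "area", "sigma")
  if (!all(need_a %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need_a, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_s %in% names(segments))) {
    stop("segments must have columns: ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(segments) == 0L) stop("segment set has zero segments", call. = FALSE)
  if (any(segments$area <= 0)) {
    stop("all segment areas must be positive", call. = FALSE)
  }
  if (any(segments$atom < 1L | segments$atom > nrow(atoms))) {
    stop("segment atom indices must refer to existing atoms", call. = FALSE)
  }
  seg_sum <- sum(segments$area)
  if (is.finite(area) && abs(seg_sum - area) > 5e-3 * area) {
    stop(sprintf(
      "segment areas sum to %.4f A^2 but header area is %.4f A^2 (>0.5%% off)",
      seg_sum, area), call. = FALSE)
  }
  structure(
    list(name = name, atoms = atoms, segments = segments,
         area = area, volume = volume, averaged = averaged),
    class = "cosmo_segments")
}

#' @export
print.cosmo_segments <- function(x, ...) {
  cat(sprintf(
    "<cosmo_segments> %s: %d atoms, %d segments, A = %.2f A^2, V = %.2f A^3%s\n",
    x$name, nrow(x$atoms), nrow(x$segments), x$area, x$volume,
    if (x$averaged) " (sigma averaged)" else ""))
  invisible(x)
}

# Split the lines of a Gaussian-dialect COSMO file into $-sections.
cosmo_sections <- function(lines) {
  idx <- grep("^\\$", lines)
  if (length(idx) == 0L) return(list())
  keys <- sub("^\\$", "", trimws(lines[idx]))
  out <- vector("list", length(idx))
  names(out) <- keys
  bounds <- c(idx, length(lines) + 1L)
  for (i in seq_along(idx)) {
    body <- lines[seq(idx[i] + 1L, bounds[i + 1L] - 1L)]
    out[[i]] <- body[nzchar(trimws(body))]
  }
  out
}

# "key = value" lookup inside a section body; strips trailing comments.
cosmo_keyval <- function(body, key) {
  pat <- paste0("^\\s*", key, "\\s*=")
  hit <- grep(pat, body, value = TRUE)
  if (length(hit) == 0L) return(NA_real_)
  val <- sub(pat, "", hit[1])
  val <- sub("#.*$", "", val)
  as.numeric(strsplit(trimws(val), "\\s+")[[1]][1])
}

#' Parse a Gaussian-dialect COSMO segment file
#'
#' Reads the `.cosmo` file written by a Gaussian (rev. C.01, SCRF=COSMORS)
#' continuum-solvation calculation: atom block (`$coord_rad`, coordinates in
#' atomic units), cavity area/volume (`$cosmo_data`, in A^2 / A^3) and the
#' surface segment block (`$segment_information`, positions in atomic units,
#' areas in A^2, charge densities in e/A^2). Coordinates are converted to
#' Angstrom. Other COSMO dialects are rejected.
#'
#' @param path Path to the `.cosmo` file.
#' @return A [segment_set()] with raw (unaveraged) charge densities.
#' @export
parse_cosmo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sec <- cosmo_sections(lines)
  if (length(sec) == 0L) {
    stop("not a Gaussian-dialect COSMO file (no $-sections): ", path,
         call. = FALSE)
  }
  for (required in c("coord_rad", "segment_information")) {
    if (!required %in% names(sec)) {
      stop("COSMO file is missing the $", required, " section: ", path,
           call. = FALSE)
    }
  }
  name <- if ("info" %in% names(sec) && length(sec$info)) {
    trimws(sec$info[1])
  } else {
    sub("\\.cosmo$", "", basename(path))
  }
  area <- volume <- NA_real_
  if ("cosmo_data" %in% names(sec)) {
    area <- cosmo_keyval(sec$cosmo_data, "area")
    volume <- cosmo_keyval(sec$cosmo_data, "volume")
  }

  parse_rows <- function(body, what) {
    body <- body[!grepl("^\\s*#", body)]
    if (length(body) == 0L) {
      stop("COSMO $", what, " section contains no data rows", call. = FALSE)
    }
    rows <- lapply(strsplit(trimws(body), "\\s+"), identity)
    n <- unique(lengths(rows))
    if (length(n) != 1L) {
      stop("ragged rows in COSMO $", what, " section", call. = FALSE)
    }
    do.call(rbind, rows)
  }

  am <- parse_rows(sec$coord_rad, "coord_rad")
  if (ncol(am) < 5L) stop("malformed $coord_rad block", call. = FALSE)
  atoms <- data.frame(
    element = am[, 5],
    x = as.numeric(am[, 2]) * BOHR,
    y = as.numeric(am[, 3]) * BOHR,
    z = as.numeric(am[, 4]) * BOHR,
    stringsAsFactors = FALSE)

  sm <- parse_rows(sec$segment_information, "segment_information")
  if (ncol(sm) < 8L) stop("malformed $segment_information block", call. = FALSE)
  segments <- data.frame(
    atom = as.integer(sm[, 2]),
    x = as.numeric(sm[, 3]) * BOHR,
    y = as.numeric(sm[, 4]) * BOHR,
    z = as.numeric(sm[, 5]) * BOHR,
    area = as.numeric(sm[, 7]),
    sigma = as.numeric(sm[, 8]))
  if (anyNA(segments)) stop("non-numeric fields in segment block", call. = FALSE)

  if (!is.finite(area)) area <- sum(segments$area)
  segment_set(name, atoms, segments, area = area, volume = volume,
              averaged = FALSE)
}

#' Write a segment set as a Gaussian-dialect COSMO file
#'
#' Counterpart of [parse_cosmo()]; used by the fixture generator so that all
#' tests exercise the real parser. Coordinates are written in atomic units.
#'
#' @param seg A [segment_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cosmo <- function(seg, path) {
  a <- seg$atoms
  s <- seg$segments
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$info")
  w("%s", seg$name)
  w("$cosmo_data")
  w("  fepsi  = 1.0000")
  w("  area   = %.10f # [A**2]", seg$area)
  w("  volume = %.10f # [A**3]", seg$volume)
  w("$coord_rad")
  w("#atom   x [au]              y [au]              z [au]        element  radius [A]")
  for (i in seq_len(nrow(a))) {
    w(" %4d  %18.10f %18.10f %18.10f   %-2s   2.00",
      i, a$x[i] / BOHR, a$y[i] / BOHR, a$z[i] / BOHR, a$element[i])
  }
  w("$screening_charge")
  w("  cosmo  = %.10f", sum(s$sigma * s$area))
  w("$segment_information")
  w("# n  atom     x [au]             y [au]             z [au]       charge [e]      area [A**2]     charge/area [e/A**2]  potential")
  for (i in seq_len(nrow(s))) {
    w(" %5d %4d %18.10f %18.10f %18.10f %16.10e %16.10e %20.10e  0.0",
      i, s$atom[i], s$x[i] / BOHR, s$y[i] / BOHR, s$z[i] / BOHR,
      s$sigma[i] * s$area[i], s$area[i], s$sigma[i])
  }
  invisible(path)
}

#' Distance-weighted averaging of segment charge densities
#'
#' Replaces every segment's raw screening charge density by the standard
#' COSMO-SAC average over all segments, with weights combining the segment
#' radius \eqn{r_n = \sqrt{a_n/\pi}}, the averaging radius `r_av`, and a
#' Gaussian decay in the inter-segment distance:
#' \deqn{\sigma_m = \frac{\sum_n \sigma_n \frac{r_n^2 r_{av}^2}{r_n^2+r_{av}^2}
#'   \exp(-f_{decay}\, d_{mn}^2/(r_n^2+r_{av}^2))}{\sum_n
#'   \frac{r_n^2 r_{av}^2}{r_n^2+r_{av}^2}
#'   \exp(-f_{decay}\, d_{mn}^2/(r_n^2+r_{av}^2))}}
#' Areas are unchanged.
#'
#' @param seg A [segment_set()] with raw charge densities.
#' @param r_av Averaging radius in Angstrom (default from [cosmosac_params()]).
#' @param f_decay Dimensionless decay factor (default from the 2010 set).
#' @return The segment set with averaged `sigma` and `averaged = TRUE`.
#' @export
average_charge_density <- function(seg, r_av = NULL, f_decay = NULL) {
  pars <- cosmosac_params()
  if (is.null(r_av)) r_av <- pars$r_av
  if (is.null(f_decay)) f_decay <- pars$f_decay
  stopifnot(r_av > 0)
  s <- seg$segments
  n <- nrow(s)
  if (n == 1L) {
    seg$averaged <- TRUE
    return(seg)
  }
  rn2 <- s$area / pi
  rav2 <- r_av^2
  d2 <- as.matrix(stats::dist(cbind(s$x, s$y, s$z)))^2
  denom <- rn2 + rav2                       # per source segment n
  wgt <- sweep(exp(-f_decay * sweep(d2, 2L, denom, "/")), 2L,
               rn2 * rav2 / denom, "*")
  seg$segments$sigma <- as.vector(wgt %*% s$sigma) / rowSums(wgt)
  seg$averaged <- TRUE
  seg
}

#' Construct a sigma-profile
#'
#' @param values 51 x 3 matrix of area-weighted profile values
#'   \eqn{A_i p_i(\sigma)} in A^2; columns are the `nhb`, `oh`, `ot`
#'   hydrogen-bond classes.
#' @param volume Cavity volume in A^3.
#' @param name Species name.
#' @return Object of class `sigma_profile`. The `area` field is the exact
#'   bin sum, so area conservation holds by construction.
#' @export
sigma_profile <- function(values, volume = NA_real_, name = "profile") {
  values <- as.matrix(values)
  if (nrow(values) != 51L || ncol(values) != 3L) {
    stop("sigma-profile values must be a 51 x 3 matrix", call. = FALSE)
  }
  if (any(values < 0)) stop("sigma-profile bins must be >= 0", call. = FALSE)
  dimnames(values) <- list(NULL, HB_CLASSES)
  structure(
    list(name = name, sigma = sigma_grid(), values = values,
         area = sum(values), volume = volume),
    class = "sigma_profile")
}

#' @export
print.sigma_profile <- function(x, ...) {
  byc <- colSums(x$values)
  cat(sprintf(
    "<sigma_profile> %s: A = %.2f A^2 (nhb %.1f, oh %.1f, ot %.1f), V = %.2f A^3\n",
    x$name, x$area, byc[["nhb"]], byc[["oh"]], byc[["ot"]], x$volume))
  invisible(x)
}

# Bin segments onto the 51-bin grid with two-point linear interpolation and
# the HB switching function. `cls` is the per-segment class ("nhb"/"oh"/"ot").
# Returns a 51 x 3 matrix whose total equals sum(area) exactly.
bin_segments <- function(sigma, area, cls, sigma_hb = NULL) {
  pars <- cosmosac_params()
  if (is.null(sigma_hb)) sigma_hb <- pars$sigma_hb
  grid <- sigma_grid()
  lo <- grid[1L]; hi <- grid[51L]
  if (any(sigma < lo - 1e-15 | sigma > hi + 1e-15)) {
    warning("segment sigma outside [", lo, ", ", hi,
            "] e/A^2; clamped to end bins", call. = FALSE)
  }
  sig <- pmin(pmax(sigma, lo), hi)
  pos <- (sig - lo) / SIGMA_STEP
  k <- pmin(floor(pos), 50)              # guard exact upper node
  frac <- pos - k                        # weight of upper neighbor
  # HB part of an OH/OT segment, switched off for near-neutral surface
  p_hb <- 1 - exp(-sig^2 / (2 * sigma_hb^2))
  out <- matrix(0, 51L, 3L, dimnames = list(NULL, HB_CLASSES))
  add <- function(bin, class, amount) {
    keep <- amount != 0
    if (!any(keep)) return(invisible())
    tab <- rowsum(amount[keep], bin[keep])
    ids <- as.integer(rownames(tab))
    out[ids, class] <<- out[ids, class] + tab[, 1L]
  }
  for (cl in HB_CLASSES) {
    sel <- cls == cl
    if (!any(sel)) next
    a <- area[sel]; kk <- k[sel] + 1L; ff <- frac[sel]
    if (cl == "nhb") {
      add(kk, "nhb", a * (1 - ff))
      add(kk + 1L, "nhb", a * ff)
    } else {
      hb <- p_hb[sel]
      add(kk, cl, a * (1 - ff) * hb)
      add(kk + 1L, cl, a * ff * hb)
      add(kk, "nhb", a * (1 - ff) * (1 - hb))
      add(kk + 1L, "nhb", a * ff * (1 - hb))
    }
  }
  out
}

#' Bin an averaged segment set into a three-class sigma-profile
#'
#' Each segment's area is apportioned linearly between the two neighboring
#' grid nodes. Segments owned by hydrogen-bonding atoms (classes `oh` for
#' hydroxyl oxygen/hydrogen, `ot` for other N/O/F and their H) contribute to
#' the HB class weighted by the Gaussian switching function
#' \eqn{P^{HB}(\sigma) = 1 - \exp(-\sigma^2/2\sigma_0^2)} with
#' \eqn{\sigma_0 = 0.007} e/A^2, the remainder to `nhb`, so near-neutral
#' surface counts as non-hydrogen-bonding. Total area is conserved exactly.
#'
#' @param seg Averaged [segment_set()].
#' @param hb_atom_classes Character vector of length `nrow(seg$atoms)` with
#'   values `"nhb"`, `"oh"`, `"ot"`; `NULL` means all atoms `nhb`.
#' @param name Profile name (defaults to the segment-set name).
#' @return A [sigma_profile()].
#' @export
build_profile <- function(seg, hb_atom_classes = NULL, name = seg$name) {
  if (!isTRUE(seg$averaged)) {
    warning("building a profile from unaveraged charge densities",
            call. = FALSE)
  }
  na <- nrow(seg$atoms)
  if (is.null(hb_atom_classes)) hb_atom_classes <- rep("nhb", na)
  if (length(hb_atom_classes) != na) {
    stop("hb_atom_classes must have one entry per atom", call. = FALSE)
  }
  if (!all(hb_atom_classes %in% HB_CLASSES)) {
    stop("hb classes must be one of: ", paste(HB_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  cls <- hb_atom_classes[seg$segments$atom]
  vals <- bin_segments(seg$segments$sigma, seg$segments$area, cls)
  sigma_profile(vals, volume = seg$volume, name = name)
}

#' Read / write the sigma-profile text format
#'
#' The `.sigma` file carries `# key: value` header lines (name, area,
#' volume) followed by 51 data rows. Rows have either 2 columns (sigma and a
#' single area column, loaded as all-NHB) or 4 columns (sigma plus the nhb,
#' oh, ot class areas). Values are stored with 17 significant digits so a
#' write/read round trip is bit-exact.
#'
#' @param path File path.
#' @return [read_sigma()] returns a [sigma_profile()]; [write_sigma()]
#'   returns `path` invisibly.
#' @export
read_sigma <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != 51L) {
    stop("sigma file must have 51 data rows, found ", length(body), ": ",
         path, call. = FALSE)
  }
  rows <- strsplit(trimws(body), "\\s+")
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L || !ncols %in% c(2L, 4L)) {
    bad <- which(lengths(rows) != lengths(rows)[1])[1]
    stop("malformed sigma file row (data line ",
         if (length(ncols) != 1L) bad else 1L,
         "): expected 2 or 4 columns", call. = FALSE)
  }
  num <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), nrow = 51L, byrow = TRUE))
  if (anyNA(num)) {
    bad <- which(apply(num, 1L, anyNA))[1]
    stop("malformed sigma file row (data line ", bad, "): non-numeric field",
         call. = FALSE)
  }
  if (max(abs(num[, 1] - sigma_grid())) > 1e-12) {
    stop("sigma file grid differs from the standard 51-bin grid", call. = FALSE)
  }
  vals <- matrix(0, 51L, 3L)
  if (ncols == 2L) vals[, 1L] <- num[, 2L] else vals[, 1:3] <- num[, 2:4]
  volume <- if (!is.null(meta[["volume[A^3]"]])) {
    as.numeric(meta[["volume[A^3]"]])
  } else NA_real_
  nm <- if (!is.null(meta$name)) meta$name else basename(path)
  sigma_profile(vals, volume = volume, name = nm)
}

#' @rdname read_sigma
#' @param profile A [sigma_profile()].
#' @param classes `"three"` writes the 4-column NHB/OH/OT variant,
#'   `"single"` collapses the classes into one area column.
#' @export
write_sigma <- function(profile, path, classes = c("three", "single")) {
  classes <- match.arg(classes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# name: %s", profile$name),
    sprintf("# area[A^2]: %.17g", profile$area),
    sprintf("# volume[A^3]: %.17g", profile$volume),
    sprintf("# classes: %s",
            if (classes == "three") "nhb oh ot" else "total")), con)
  g <- sigma_grid()
  if (classes == "three") {
    writeLines(sprintf("%7.4f %24.17g %24.17g %24.17g", g,
                       profile$values[, 1], profile$values[, 2],
                       profile$values[, 3]), con)
  } else {
    writeLines(sprintf("%7.4f %24.17g", g, rowSums(profile$values)), con)
  }
  invisible(path)
}
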
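#' Monomer unit counts of a virtual macromolecule
#'
#' Determines how many monomer units of each type a polymer of molar mass
#' `M_poly` contains. For a homopolymer this is `round(M_poly / m)`. For a
#' copolymer with molar unit ratio `ratio`, the total unit count follows
#' from the ratio-weighted mean monomer mass and is split per type before
#' rounding to the nearest integer.
#'
#' @param M_poly Target polymer molar mass in g/mol.
#' @param monomer_masses Numeric vector of monomer molar masses in g/mol,
#'   one per unit type.
#' @param ratio Molar fractions of the unit types (summing to 1); ignored
#'   for homopolymers.
#' @return Integer vector of unit counts, one per type.
#' @examples
#' count_units(32000, 44.053)  # poly(vinyl alcohol): 726 units
#' @export
count_units <- function(M_poly, monomer_masses, ratio = NULL) {
  stopifnot(all(monomer_masses > 0), M_poly > 0)
  if (M_poly < min(monomer_masses)) {
    stop("M_poly (", M_poly, " g/mol) is smaller than one monomer",
         call. = FALSE)
  }
  if (length(monomer_masses) == 1L) {
    return(as.integer(round(M_poly / monomer_masses)))
  }
  if (is.null(ratio) || length(ratio) != length(monomer_masses)) {
    stop("copolymers need one molar ratio entry per monomer type",
         call. = FALSE)
  }
  if (abs(sum(ratio) - 1) > 1e-8) {
    stop("copolymer molar ratio must sum to 1", call. = FALSE)
  }
  mbar <- sum(ratio * monomer_masses)
  n_total <- M_poly / mbar
  counts <- as.integer(round(ratio * n_total))
  if (any(counts < 1L)) {
    stop("M_poly too small: rounded unit count below 1 for some type",
         call. = FALSE)
  }
  counts
}

#' Specify a virtual macromolecule built from an oligomer
#'
#' Describes how a polymer sigma-profile is to be constructed from a short
#' oligomer's COSMO data: which atoms form the central monomer unit(s) to
#' replicate, the monomer molar masses, and the target polymer molar mass.
#' Unit counts `N_units` per type are derived with [count_units()]; the
#' number of *additional* copies of each central unit is
#' `n_rep = N_units - n_in_oligomer` (trimer homopolymer: `N - 3` extra
#' copies, i.e. the central unit ends up present `N - 2` times next to the
#' two edge units; ABAB tetramer: `N_type - 2` extras per type).
#'
#' @param oligomer An averaged [segment_set()] of the capped oligomer.
#' @param units List of integer vectors: atom indices of the central unit of
#'   each monomer type. Sets must be disjoint and non-empty; end-cap atoms
#'   belong to the edge units and are never listed here.
#' @param monomer_masses Monomer molar mass per type, g/mol.
#' @param M_poly Target polymer molar mass, g/mol.
#' @param ratio Copolymer molar unit ratio (`NULL` for homopolymers).
#' @param n_in_oligomer Units of each type already present in the oligomer;
#'   defaults to 3 for homopolymers (trimer) and 2 per type for copolymers
#'   (alternating tetramer).
#' @param unit_volume Cavity volume attributed to one unit of each type, in
#'   A^3; defaults to apportioning the oligomer volume by unit surface area.
#' @param hb_atom_classes Per-atom HB classes for profile binning.
#' @param n_rep Override for the additional-copy counts (e.g. `0` to recover
#'   the plain oligomer); must be `>= 0`.
#' @param name Polymer name.
#' @return Object of class `polymer_spec`.
#' @export
polymer_spec <- function(oligomer, units, monomer_masses, M_poly,
                         ratio = NULL, n_in_oligomer = NULL,
                         unit_volume = NULL, hb_atom_classes = NULL,
                         n_rep = NULL, name = oligomer$name) {
  stopifnot(inherits(oligomer, "cosmo_segments"), is.list(units))
  ntype <- length(units)
  if (ntype == 0L || any(lengths(units) == 0L)) {
    stop("each monomer type needs a non-empty atom-index set", call. = FALSE)
  }
  all_idx <- unlist(units)
  if (anyDuplicated(all_idx)) {
    stop("central-unit atom-index sets must be disjoint", call. = FALSE)
  }
  if (any(all_idx < 1L | all_idx > nrow(oligomer$atoms))) {
    stop("unit atom indices outside the oligomer atom range", call. = FALSE)
  }
  if (length(monomer_masses) != ntype) {
    stop("need one monomer mass per unit type", call. = FALSE)
  }
  if (is.null(n_in_oligomer)) {
    n_in_oligomer <- if (ntype == 1L) 3L else rep(2L, ntype)
  }
  if (is.null(n_rep)) {
    counts <- count_units(M_poly, monomer_masses, ratio)
    if (any(counts < n_in_oligomer)) {
      stop("derived unit counts (", paste(counts, collapse = ", "),
           ") below the units already present in the oligomer", call. = FALSE)
    }
    n_rep <- counts - n_in_oligomer
  } else {
    counts <- n_rep + n_in_oligomer
    if (any(n_rep < 0)) stop("replication count < 0", call. = FALSE)
  }

  seg_atom <- oligomer$segments$atom
  unit_area <- vapply(units, function(idx) {
    sum(oligomer$segments$area[seg_atom %in% idx])
  }, numeric(1))
  if (is.null(unit_volume)) {
    unit_volume <- oligomer$volume * unit_area / sum(oligomer$segments$area)
  }
  structure(
    list(oligomer = oligomer, units = units,
         monomer_masses = monomer_masses, M_poly = M_poly, ratio = ratio,
         n_in_oligomer = as.integer(n_in_oligomer),
         N_units = as.integer(counts), n_rep = as.integer(n_rep),
         unit_area = unit_area, unit_volume = unit_volume,
         hb_atom_classes = hb_atom_classes, name = name),
    class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf(
    "<polymer_spec> %s: M_poly = %g g/mol, %d unit type(s), N_units = %s, n_rep = %s\n",
    x$name, x$M_poly, length(x$units),
    paste(x$N_units, collapse = "/"), paste(x$n_rep, collapse = "/")))
  invisible(x)
}

#' Build a polymer sigma-profile by monomer-unit replication
#'
#' The averaged oligomer is binned into a three-class profile; the binned
#' contribution of each central unit's segments is then added `n_rep` more
#' times per type. Because binning is linear in the segments, this equals
#' explicit segment duplication bin-exactly. Total area and cavity volume
#' accumulate additively.
#'
#' @param spec A [polymer_spec()].
#' @return A [sigma_profile()] of the virtual macromolecule.
#' @export
replicate_profile <- function(spec) {
  olig <- spec$oligomer
  if (!isTRUE(olig$averaged)) {
    stop("averaging must precede replication: oligomer sigma is raw",
         call. = FALSE)
  }
  na <- nrow(olig$atoms)
  cls_atom <- spec$hb_atom_classes
  if (is.null(cls_atom)) cls_atom <- rep("nhb", na)
  cls <- cls_atom[olig$segments$atom]
  vals <- bin_segments(olig$segments$sigma, olig$segments$area, cls)
  vol <- olig$volume
  for (t in seq_along(spec$units)) {
    if (spec$n_rep[t] == 0L) next
    sel <- olig$segments$atom %in% spec$units[[t]]
    unit_vals <- bin_segments(olig$segments$sigma[sel],
                              olig$segments$area[sel], cls[sel])
    vals <- vals + spec$n_rep[t] * unit_vals
    vol <- vol + spec$n_rep[t] * spec$unit_volume[t]
  }
  sigma_profile(vals, volume = vol, name = spec$name)
}

#' Replicated cavity area and volume of a virtual macromolecule
#'
#' Applies the same additive replication rule to the total cavity surface
#' area and volume, which feed the Staverman-Guggenheim size and shape
#' parameters of the polymer.
#'
#' @param spec A [polymer_spec()].
#' @return List with elements `area` (A^2) and `volume` (A^3).
#' @export
replicate_area_volume <- function(spec) {
  olig <- spec$oligomer
  list(area = sum(olig$segments$area) + sum(spec$n_rep * spec$unit_area),
       volume = olig$volume + sum(spec$n_rep * spec$unit_volume))
}
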
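#' Universal COSMO-SAC parameter set
#'
#' Returns the substance-independent parameters of the COSMO-SAC-2010 model
#' and its dispersive (dsp) extension, as pinned by the open-source reference
#' implementation. Segment-level energies are in kcal/mol with screening
#' charge densities in e/A^2 and areas in A^2.
#'
#' @param set Parameter-set identifier; only `"2010"` is defined.
#' @return Named list of constants.
#' @export
cosmosac_params <- function(set = "2010") {
  if (!identical(set, "2010")) {
    stop("unknown parameter set '", set, "'; available: '2010'", call. = FALSE)
  }
  list(
    set       = "2010",
    a_eff     = 7.25,       # effective segment contact area [A^2]
    r_av      = 0.5,        # sigma-averaging radius [A]
    f_decay   = 3.57,       # averaging Gaussian decay factor [-]
    sigma_hb  = 0.007,      # HB switching-function width [e/A^2]
    A_ES      = 6525.69,    # misfit constant [kcal A^4 mol^-1 e^-2]
    B_ES      = 1.4859e8,   # misfit T-dependence [kcal A^4 K^2 mol^-1 e^-2]
    c_hb_ohoh = 4013.78,    # OH-OH hydrogen-bond constant [kcal A^4 mol^-1 e^-2]
    c_hb_otot = 932.31,     # OT-OT
    c_hb_ohot = 3016.43,    # OH-OT
    R_kcal    = 1.987204258640832e-3,  # gas constant [kcal mol^-1 K^-1]
    z         = 10,         # SG coordination number
    r0        = 66.69,      # SG volume normalizer [A^3]
    q0        = 79.53,      # SG area normalizer [A^2]
    w_dsp     = 0.27027     # dispersion Margules prefactor [-]
  )
}

#' The fixed 51-bin screening-charge-density grid
#'
#' Equispaced grid from -0.025 to +0.025 e/A^2 on which all sigma-profiles
#' are binned. The grid is the de-facto standard of COSMO-SAC sigma files.
#'
#' @return Numeric vector of length 51.
#' @export
sigma_grid <- function() seq(-0.025, 0.025, length.out = 51L)

# grid spacing [e/A^2]
SIGMA_STEP <- 0.001

# Bohr radius [A]; COSMO files carry coordinates in atomic units
BOHR <- 0.52917721067

# molar gas constant [J mol^-1 K^-1]
RGAS <- 8.314462618

# sigma-profile hydrogen-bond classes, in storage order
HB_CLASSES <- c("nhb", "oh", "ot")
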
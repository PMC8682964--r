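#' Model parameters for the Integrated Oscillator Model
#'
#' Returns the full parameter set of the IOM as a named list.  Units follow
#' the model's internal convention: time in ms, voltage in mV, conductance in
#' pS, current in fA, concentration in uM (glucose in mM).  All fluxes are
#' referenced to cytosolic volume (uM/ms); mitochondrial pool equations carry
#' the volume factor \code{gamma} = Vcyt/Vmito.
#'
#' The defaults encode the control condition used throughout the package's
#' scenario presets: 11 mM glucose, \code{gkca} = 150 pS, \code{vpdh} =
#' 2 uM/ms (the active-metabolic-oscillation regime), \code{p21} =
#' 0.013 uM/ms.  The experimentally motivated knobs are:
#' \describe{
#'   \item{\code{vpdh}}{maximum pyruvate dehydrogenase rate; the main regime
#'     knob (0.4 = passive metabolic oscillations, 2 = active, also 3 and 7).}
#'   \item{\code{gkca}}{Ca2+-activated K+ conductance (pS); 150 for slow
#'     bursting, 600 for compound bursting.}
#'   \item{\code{ktt}}{K(ATP) dissociation constant for ATP4- (uM); raised
#'     from 1 to 2 to emulate diazoxide.}
#'   \item{\code{vk}}{K+ Nernst potential (mV); raised from -75 to -70 to
#'     emulate KCl depolarization.}
#'   \item{\code{p21}, \code{p22}}{slope and intercept of the mitochondrial
#'     Ca2+ uniporter's dependence on the inner-membrane potential.}
#'   \item{\code{glucose}}{bath glucose (mM), the glucokinase input.}
#' }
#'
#' @param ... name = value overrides of any default parameter.
#' @return A named list of class \code{"iom_parameters"}.
#' @examples
#' p <- iom_parameters(vpdh = 0.4)
#' p$vpdh
#' @export
iom_parameters <- function(...) {
  p <- list(
    ## -- electrical module -------------------------------------------------
    cm     = 5300,    # membrane capacitance (fF)
    gca    = 1000,    # Ca2+ channel conductance (pS)
    vca    = 25,      # Ca2+ reversal potential (mV)
    vm     = -20,     # half-activation of m_inf (mV)
    sm     = 12,      # slope of m_inf (mV)
    gk     = 2700,    # delayed-rectifier conductance (pS)
    vk     = -75,     # K+ Nernst potential (mV); -70 under KCl
    vn     = -16,     # half-activation of n_inf (mV)
    sn     = 5,       # slope of n_inf (mV)
    taun   = 20,      # delayed-rectifier time constant (ms)
    gkca   = 150,     # K(Ca) conductance (pS)
    kkca   = 0.5,     # K(Ca) half-activation Ca2+ (uM)
    qkca   = 2,       # K(Ca) Hill exponent
    gkatp  = 18000,   # maximal K(ATP) conductance (pS)
    ktt    = 1,       # K(ATP) ATP4- dissociation constant (uM); 2 under Dz
    ktd    = 26,      # K(ATP) ADP3- dissociation constant (uM)
    kdd    = 17,      # K(ATP) MgADP dissociation constant (uM)
    ## -- Ca2+ handling -----------------------------------------------------
    fca     = 0.01,    # cytosolic free-Ca2+ fraction
    alpha   = 4.5e-6,  # current-to-flux conversion (uM fA^-1 ms^-1)
    kpmca   = 0.1,     # plasma-membrane Ca2+ ATPase rate (ms^-1)
    kserca  = 0.4,     # SERCA pump rate (ms^-1)
    pleak   = 2e-4,    # ER leak permeability (ms^-1)
    sigmaer = 31,      # cytosol/ER volume ratio
    fer     = 0.01,    # ER free-Ca2+ fraction
    deltam  = 0.1,     # mito-flux weight in the Ca_c balance (volume conv.)
    ## -- glycolysis --------------------------------------------------------
    glucose = 11,      # bath glucose (mM)
    vgk     = 0.0092,  # maximal glucokinase rate (uM/ms)
    kgk     = 8,       # glucokinase S0.5 (mM)
    ngk     = 3,       # glucokinase Hill coefficient (effective, lumped)
    kappa   = 0.1,     # G6P<->F6P fast-equilibrium fraction
    vpfk    = 0.02,    # maximal PFK rate (uM/ms)
    k1      = 30,      # PFK AMP^2 dissociation constant (uM^2)
    k2      = 0.04,    # PFK FBP^2 dissociation constant (uM^2)
    k3      = 50000,   # PFK F6P^2 dissociation constant (uM^2)
    k4      = 4000,    # PFK ATP^2 dissociation constant (uM^2)
    f13     = 0.02,    # AMP/F6P interaction factor
    f23     = 0.2,     # FBP/F6P interaction factor
    f41     = 20,      # ATP/AMP interaction factor
    f42     = 20,      # ATP/FBP interaction factor
    f43     = 20,      # ATP/F6P interaction factor
    lampfk  = 0.06,    # relative activity of non-fully-activated PFK states
    kgpdh   = 3,       # GPDH Ca_m half-activation constant (uM^2)
    ## -- mitochondria ------------------------------------------------------
    vpdh     = 2,      # maximal PDH rate (regime knob)
    knadhpdh = 0.2,    # PDH inhibition constant in NADH_m/NAD_m
    nadtot   = 1000,   # total mitochondrial NAD(H) (uM)
    vo       = 0.18,   # maximal NADH oxidation (respiration) rate (uM/ms)
    ko       = 2000,   # NADH_m half-saturation of J_O (uM)
    psio     = 190,    # psi_m inhibition midpoint of respiration (mV)
    so       = 5,      # slope of the psi_m inhibition of respiration (mV)
    kres     = 170,    # H+ flux per unit NADH-equivalent oxidized (lumped)
    vf1f0    = 0.06,   # maximal ATP synthase rate (uM/ms)
    kf1f0    = 2000,   # ADP_m half-saturation of ATP synthase (uM)
    psif     = 160,    # psi_m half-activation of ATP synthase (mV)
    sf       = 14,     # slope of psi_m activation of ATP synthase (mV)
    vant     = 0.0016, # maximal adenine nucleotide translocator rate (uM/ms)
    kant     = 1,      # ATP_m/ADP_m half-saturation of ANT
    kantc    = 100,    # cytosolic ADP half-saturation of ANT (uM)
    fant     = 0.0185, # ANT voltage sensitivity, F/(2RT) (mV^-1)
    p17      = 0.01,   # proton-leak scale (uM/ms)
    p18      = 0.04,   # proton-leak voltage steepness (mV^-1)
    p21      = 0.013,  # uniporter psi_m slope (uM/ms per mV*uM, printed units)
    p22      = 1.65,   # uniporter intercept
    p23      = 30,     # Na+/Ca2+ exchanger rate (uM/ms)
    p24      = -0.05,  # Na+/Ca2+ exchanger voltage sensitivity (mV^-1)
    fm       = 2e-5,   # mito free-Ca2+ fraction x volume factor
    cmito    = 6000,   # inner-membrane capacitance (uM/mV)
    gamma    = 0.0875, # mito-pool flux scaling (volume/buffering lumped)
    ## -- cytosolic nucleotides ---------------------------------------------
    actot   = 2500,    # total cytosolic adenine nucleotides (uM)
    amtot   = 15000,   # total mitochondrial adenine nucleotides (uM)
    khyd    = 2e-6,    # basal ATP hydrolysis rate (ms^-1)
    khydca  = 3e-5,    # Ca2+-pump ATP hydrolysis rate (ms^-1 uM^-1)
    deltamv = 1        # ANT weight in the ADP_c balance (volume conv.)
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_parameters(p)
  class(p) <- c("iom_parameters", "list")
  p
}

## parameters that must be strictly positive
.positive_params <- c(
  "cm", "gca", "gk", "taun", "kkca", "qkca", "ktt", "ktd", "kdd",
  "fca", "sigmaer", "fer", "vgk", "kgk", "ngk", "kappa",
  "vpfk", "k1", "k2", "k3", "k4", "f13", "f23", "f41", "f42", "f43",
  "kgpdh", "knadhpdh", "nadtot", "vo", "ko", "so", "kres", "vf1f0",
  "kf1f0", "sf", "vant", "kant", "kantc", "fm", "cmito", "gamma", "actot", "amtot"
)

validate_parameters <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-finite or non-scalar parameter(s): ",
         paste(names(p)[!num], collapse = ", "))
  bad <- .positive_params[vapply(.positive_params,
                                 function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "))
  nonneg <- c("gkca", "gkatp", "glucose", "khyd", "khydca", "kpmca", "pleak",
              "kserca",
              "lampfk", "deltam", "deltamv", "alpha", "p17", "p23")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be >= 0: ", paste(bad, collapse = ", "))
  invisible(p)
}

#' @export
print.iom_parameters <- function(x, ...) {
  cat("<iom_parameters> ", length(x), " parameters\n", sep = "")
  knobs <- c("glucose", "vpdh", "gkca", "gkatp", "ktt", "vk", "p21")
  for (k in knobs) cat(sprintf("  %-8s %g\n", k, x[[k]]))
  invisible(x)
}

#' State variable names of the IOM
#'
#' The 11 state variables, in integration order: membrane potential \code{v}
#' (mV), delayed-rectifier activation \code{n}, cytosolic / ER /
#' mitochondrial free Ca2+ \code{cac}, \code{caer}, \code{cam} (uM),
#' glycolytic intermediates \code{f6p}, \code{fbp} (uM), mitochondrial
#' \code{nadhm}, \code{adpm} (uM), inner-membrane potential \code{psim} (mV),
#' and cytosolic \code{adpc} (uM).
#'
#' @return Character vector of length 11.
#' @export
iom_state_names <- function() {
  c("v", "n", "cac", "caer", "cam", "f6p", "fbp",
    "nadhm", "adpm", "psim", "adpc")
}

#' Default initial state
#'
#' A documented, fixed starting point used by [equilibrate_iom()].  It is not
#' on any attractor; simulations discard a transient before analysis.
#'
#' @return Named numeric vector over [iom_state_names()].
#' @export
iom_initial_state <- function() {
  c(v = -63, n = 0.01, cac = 0.15, caer = 120, cam = 0.2,
    f6p = 150, fbp = 5, nadhm = 500, adpm = 8000, psim = 160,
    adpc = 800)
}

## canonical order in which parameters are passed to the compiled RHS
.param_order <- c(
  "cm", "gca", "vca", "vm", "sm", "gk", "vk", "vn", "sn", "taun",
  "gkca", "kkca", "qkca", "gkatp", "ktt", "ktd", "kdd",
  "fca", "alpha", "kpmca", "kserca", "pleak", "sigmaer", "fer", "deltam",
  "glucose", "vgk", "kgk", "ngk", "kappa", "vpfk",
  "k1", "k2", "k3", "k4", "f13", "f23", "f41", "f42", "f43", "lampfk",
  "kgpdh", "vpdh", "knadhpdh", "nadtot", "vo", "ko", "psio", "so", "kres",
  "vf1f0", "kf1f0", "psif", "sf", "vant", "kant", "kantc", "fant",
  "p17", "p18", "p21", "p22", "p23", "p24", "fm", "cmito", "gamma",
  "actot", "amtot", "khyd", "khydca", "deltamv",
  ## runtime controls appended for the integrator (not user parameters)
  "clamp_cac", "clamp_level"
)

## parameter list -> numeric vector for the compiled RHS
param_vector <- function(p, clamp_cac = FALSE, clamp_level = 0) {
  p$clamp_cac <- as.numeric(clamp_cac)
  p$clamp_level <- clamp_level
  unlist(p[.param_order])
}
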
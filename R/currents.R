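## Electrical module: ionic currents, K(ATP) gating, membrane and Ca2+
## balance equations.  All functions are vectorized over their first
## arguments so they can be applied to whole trajectories.

#' Instantaneous Ca2+ channel activation
#'
#' Boltzmann sigmoid \eqn{m_\infty(V) = 1/(1+\exp((v_m - V)/s_m))}.
#'
#' @param v Membrane potential (mV).
#' @param params An [iom_parameters()] list.
#' @return Activation in (0, 1).
#' @export
m_inf <- function(v, params = iom_parameters()) {
  1 / (1 + exp((params$vm - v) / params$sm))
}

#' Steady-state delayed-rectifier activation
#'
#' @inheritParams m_inf
#' @return Activation in (0, 1).
#' @export
n_inf <- function(v, params = iom_parameters()) {
  1 / (1 + exp((params$vn - v) / params$sn))
}

#' Nucleotide species seen by the K(ATP) channel
#'
#' The channel-regulating species are fixed fractions of the cytosolic
#' totals: MgADP = 0.165 ADP, ADP3- = 0.135 ADP, ATP4- = 0.05 ATP.
#'
#' @param atp,adp Cytosolic ATP and ADP (uM).
#' @return List with `atp`, `adp`, `mgadp`, `adp3`, `atp4` (uM).
#' @export
katp_nucleotides <- function(atp, adp) {
  if (any(atp < 0) || any(adp < 0))
    stop("nucleotide concentrations must be >= 0")
  list(atp = atp, adp = adp,
       mgadp = 0.165 * adp, adp3 = 0.135 * adp, atp4 = 0.05 * atp)
}

#' Fraction of open K(ATP) channels
#'
#' The equilibrium open fraction of the ATP-inhibited, MgADP-activated
#' K(ATP) channel:
#' \deqn{o_\infty = \frac{0.08 + 0.89 (MgADP/k_{dd})^2 + 0.16 (MgADP/k_{dd})}
#'   {(1 + MgADP/k_{dd})^2 (1 + ATP^{4-}/k_{tt} + ADP^{3-}/k_{td})}}
#' It decreases with ATP and increases with the ATP dissociation constant
#' \code{ktt} (the diazoxide knob).
#'
#' @param atp,adp Cytosolic ATP and ADP (uM).
#' @param ktt,ktd,kdd Dissociation constants for ATP4-, ADP3-, MgADP (uM).
#' @return Open fraction in (0, 1]; equals 0.08 at zero nucleotides.
#' @export
katp_open_fraction <- function(atp, adp, ktt = 1, ktd = 26, kdd = 17) {
  if (any(atp < 0) || any(adp < 0))
    stop("nucleotide concentrations must be >= 0")
  if (any(c(ktt, ktd, kdd) <= 0))
    stop("dissociation constants must be > 0")
  nuc <- katp_nucleotides(atp, adp)
  md <- nuc$mgadp / kdd
  (0.08 + 0.89 * md^2 + 0.16 * md) /
    ((1 + md)^2 * (1 + nuc$atp4 / ktt + nuc$adp3 / ktd))
}

#' K(ATP) current
#'
#' \eqn{I_{K(ATP)} = g_{K(ATP)} \, o_\infty(ATP, ADP) \, (V - V_K)} in fA.
#'
#' @inheritParams katp_open_fraction
#' @param v Membrane potential (mV).
#' @param gkatp Maximal conductance (pS).
#' @param vk K+ Nernst potential (mV).
#' @return Current (fA), outward positive.
#' @export
katp_current <- function(v, atp, adp, gkatp = 25000, vk = -75,
                         ktt = 1, ktd = 26, kdd = 17) {
  if (any(gkatp < 0)) stop("gkatp must be >= 0")
  gkatp * katp_open_fraction(atp, adp, ktt, ktd, kdd) * (v - vk)
}

#' All four membrane currents
#'
#' Computes the voltage-dependent Ca2+ current, the delayed-rectifier K+
#' current, the Ca2+-activated K+ current (Hill activation in cytosolic
#' Ca2+), and the K(ATP) current.
#'
#' @param v Membrane potential (mV).
#' @param n Delayed-rectifier activation.
#' @param cac Cytosolic Ca2+ (uM).
#' @param atp,adp Cytosolic nucleotides (uM).
#' @param params An [iom_parameters()] list.
#' @return List with `ica`, `ik`, `ikca`, `ikatp` (fA).
#' @export
membrane_currents <- function(v, n, cac, atp, adp, params = iom_parameters()) {
  p <- params
  caq <- cac^p$qkca
  list(
    ica   = p$gca * m_inf(v, p) * (v - p$vca),
    ik    = p$gk * n * (v - p$vk),
    ikca  = p$gkca * caq / (p$kkca^p$qkca + caq) * (v - p$vk),
    ikatp = katp_current(v, atp, adp, p$gkatp, p$vk, p$ktt, p$ktd, p$kdd)
  )
}

#' Membrane potential and gating derivatives
#'
#' Current balance \eqn{dV/dt = -(I_{Ca}+I_K+I_{K(Ca)}+I_{K(ATP)})/C_m} and
#' first-order relaxation of the delayed-rectifier gate.
#'
#' @param v,n Membrane potential (mV) and gating variable.
#' @param currents A list as returned by [membrane_currents()].
#' @param params An [iom_parameters()] list.
#' @return List with `dv` (mV/ms) and `dn` (1/ms).
#' @export
membrane_rhs <- function(v, n, currents, params = iom_parameters()) {
  if (params$cm <= 0) stop("membrane capacitance cm must be > 0")
  list(
    dv = -(currents$ica + currents$ik + currents$ikca + currents$ikatp) /
      params$cm,
    dn = (n_inf(v, params) - n) / params$taun
  )
}

#' Cytosolic and ER Ca2+ balance
#'
#' \deqn{dCa_c/dt = f_c[-(\alpha I_{Ca} + k_{PMCA} Ca_c)
#'   + p_{leak}(Ca_{er}-Ca_c) - k_{SERCA} Ca_c + \delta_m(J_{NaCa}-J_{uni})]}
#' \deqn{dCa_{er}/dt = -f_{er}\sigma_{er}[p_{leak}(Ca_{er}-Ca_c)
#'   - k_{SERCA} Ca_c]}
#' ATP consumption by the Ca2+ pumps is accounted for in the nucleotide
#' balance ([nucleotide_rhs()]); this function only moves Ca2+.
#'
#' @param cac,caer Cytosolic and ER free Ca2+ (uM).
#' @param ica Ca2+ current (fA).
#' @param juni,jnaca Mitochondrial uniporter influx and Na+/Ca2+ exchanger
#'   efflux (uM/ms, cytosol-referenced).
#' @param params An [iom_parameters()] list.
#' @return List with `dcac`, `dcaer` (uM/ms).
#' @export
calcium_compartment_rhs <- function(cac, caer, ica, juni, jnaca,
                                    params = iom_parameters()) {
  p <- params
  jmem <- -(p$alpha * ica + p$kpmca * cac)
  jer <- p$pleak * (caer - cac) - p$kserca * cac
  list(
    dcac  = p$fca * (jmem + jer + p$deltam * (jnaca - juni)),
    dcaer = -p$fer * p$sigmaer * jer
  )
}
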
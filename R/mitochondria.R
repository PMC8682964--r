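## Mitochondrial module: NADH production/oxidation, inner-membrane
## potential, mitochondrial Ca2+, ATP synthesis/export, and the cytosolic
## nucleotide balance including Ca2+-pump hydrolysis.

#' Pyruvate dehydrogenase flux
#'
#' \eqn{J_{PDH} = v_{PDH} \frac{1}{K + NADH_m/NAD_m} J_{GPDH}}: proportional
#' to the glycolytic input and product-inhibited through the mitochondrial
#' redox ratio.  \code{vpdh} is the principal regime knob of the model.
#'
#' @param nadhm,nadm Mitochondrial NADH and NAD+ (uM); `nadm` > 0.
#' @param jgpdh GPDH flux (uM/ms).
#' @param vpdh Maximal PDH rate.
#' @param knadhpdh Inhibition constant (dimensionless, in NADH_m/NAD_m).
#' @return Flux (uM/ms).
#' @export
pdh_flux <- function(nadhm, nadm, jgpdh, vpdh = 2, knadhpdh = 0.2) {
  if (any(nadm <= 0)) stop("nadm must be > 0")
  if (any(nadhm < 0) || any(jgpdh < 0) || any(vpdh < 0))
    stop("nadhm, jgpdh, vpdh must be >= 0")
  vpdh / (knadhpdh + nadhm / nadm) * jgpdh
}

#' Mitochondrial Ca2+ uniporter flux
#'
#' \eqn{J_{uni} = (p_{21}\,\Delta\psi_m - p_{22})\, Ca_c}: linear in the
#' cytosolic Ca2+ concentration, with an approximately linear dependence on
#' the inner-membrane potential (slope \code{p21}, intercept \code{p22}).
#' Negative only when \eqn{\Delta\psi_m < p_{22}/p_{21}}.
#'
#' @param cac Cytosolic Ca2+ (uM), >= 0.
#' @param psim Inner-membrane potential (mV).
#' @param p21,p22 Slope and intercept of the voltage dependence.
#' @return Flux (uM/ms), positive into the mitochondria.
#' @export
uniporter_flux <- function(cac, psim, p21 = 0.013, p22 = 1.65) {
  if (any(cac < 0)) stop("cac must be >= 0")
  (p21 * psim - p22) * cac
}

#' All mitochondrial fluxes
#'
#' Assembles the flux set of the mitochondrial module: PDH ([pdh_flux()]),
#' respiration-driven NADH oxidation `jo` (saturating in NADH_m, inhibited
#' at high psi_m), proton pumping `jhres = kres * jo`, ATP synthase `jf1f0`
#' (saturating in ADP_m, activated by psi_m) with proton influx
#' `jhatp = 3 jf1f0`, the adenine nucleotide translocator `jant` (exports
#' ATP_m, increasing in psi_m and ATP_m/ADP_m), the proton leak `jhleak`
#' (exponential in psi_m, the main inner-membrane charge sink), the
#' Ca2+ uniporter ([uniporter_flux()]), and the Na+/Ca2+ exchanger `jnaca`
#' (increasing in Ca_m, decreasing in Ca_c).
#'
#' @param nadhm,adpm,cam,psim Mitochondrial state (uM, uM, uM, mV).
#' @param cac Cytosolic Ca2+ (uM).
#' @param jgpdh GPDH flux (uM/ms).
#' @param adpc Cytosolic ADP (uM); the ANT exchange saturates in its
#'   cytosolic substrate.
#' @param params An [iom_parameters()] list.
#' @return List of fluxes (uM/ms): `jpdh`, `jo`, `jhres`, `jf1f0`, `jhatp`,
#'   `jant`, `jhleak`, `juni`, `jnaca`.
#' @export
mito_fluxes <- function(nadhm, adpm, cam, psim, cac, jgpdh, adpc,
                        params = iom_parameters()) {
  p <- params
  nadm <- p$nadtot - nadhm
  atpm <- p$amtot - adpm
  jo <- p$vo * nadhm / (p$ko + nadhm) / (1 + exp((psim - p$psio) / p$so))
  jf1f0 <- p$vf1f0 * adpm / (p$kf1f0 + adpm) /
    (1 + exp((p$psif - psim) / p$sf))
  rat <- atpm / pmax(adpm, .Machine$double.eps)
  jant <- p$vant * rat / (rat + p$kant) *
    (adpc / (adpc + p$kantc)) * exp(p$fant * psim)
  list(
    jpdh   = pdh_flux(nadhm, nadm, jgpdh, p$vpdh, p$knadhpdh),
    jo     = jo,
    jhres  = p$kres * jo,
    jf1f0  = jf1f0,
    jhatp  = 3 * jf1f0,
    jant   = jant,
    jhleak = p$p17 * exp(p$p18 * psim),
    juni   = uniporter_flux(cac, psim, p$p21, p$p22),
    jnaca  = p$p23 * (cam / pmax(cac, .Machine$double.eps)) *
      exp(p$p24 * psim)
  )
}

#' Mitochondrial state derivatives
#'
#' \deqn{dNADH_m/dt = \gamma(J_{PDH} - J_O), \quad
#'       dADP_m/dt = \gamma(J_{ANT} - J_{F1F0})}
#' \deqn{dCa_m/dt = f_m(J_{uni} - J_{NaCa})}
#' \deqn{d\Delta\psi_m/dt = (J_{Hres} - J_{Hatp} - J_{ANT} - J_{Hleak}
#'       - J_{NaCa} - 2 J_{uni})/C_{mito}}
#' The factor 2 on the uniporter term reflects the two charges carried per
#' Ca2+; the Na+/Ca2+ exchanger is electrogenic and appears in both the
#' Ca_m and psi_m balances.
#'
#' @param fluxes A list from [mito_fluxes()].
#' @param params An [iom_parameters()] list.
#' @return List with `dnadhm`, `dadpm`, `dcam`, `dpsim`.
#' @export
mito_rhs <- function(fluxes, params = iom_parameters()) {
  p <- params
  f <- fluxes
  list(
    dnadhm = p$gamma * (f$jpdh - f$jo),
    dadpm  = p$gamma * (f$jant - f$jf1f0),
    dcam   = p$fm * (f$juni - f$jnaca),
    dpsim  = (f$jhres - f$jhatp - f$jant - f$jhleak - f$jnaca -
                2 * f$juni) / p$cmito
  )
}

#' Cytosolic ATP hydrolysis flux
#'
#' \eqn{J_{hyd} = (k_{hyd} + k_{hyd,Ca}\, Ca_c)\, ATP_c}: basal turnover
#' plus the ATP consumed by plasma-membrane and ER Ca2+ pumps, which scales
#' with cytosolic Ca2+.  This is the hydrolysis arm of Ca2+'s feedback onto
#' metabolism.
#'
#' @param cac Cytosolic Ca2+ (uM).
#' @param atpc Cytosolic ATP (uM).
#' @param params An [iom_parameters()] list.
#' @return Flux (uM/ms).
#' @export
hydrolysis_flux <- function(cac, atpc, params = iom_parameters()) {
  (params$khyd + params$khydca * cac) * atpc
}

#' Cytosolic ADP derivative
#'
#' \eqn{dADP_c/dt = J_{hyd} - \delta_{mv} J_{ANT}}; ATP_c follows from the
#' conserved total \code{actot}.
#'
#' @param adpc Cytosolic ADP (uM).
#' @param cac Cytosolic Ca2+ (uM).
#' @param jant ANT flux (uM/ms).
#' @param params An [iom_parameters()] list.
#' @return Derivative (uM/ms).
#' @export
nucleotide_rhs <- function(adpc, cac, jant, params = iom_parameters()) {
  atpc <- params$actot - adpc
  hydrolysis_flux(cac, atpc, params) - params$deltamv * jant
}
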
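## Full model right-hand side.  `iom_rhs_r()` is the reference (pure R)
## implementation assembled from the module functions; the compiled C
## version in src/ is used by the integrator and is tested against this one.

#' Full IOM right-hand side (reference implementation)
#'
#' Assembles the derivatives of all 11 state variables from the three
#' biophysical modules.  Under a cytosolic Ca2+ clamp the Ca_c derivative
#' is replaced by 0 while every other equation reads the clamped value.
#'
#' @param t Time (ms); the model is autonomous, `t` is ignored.
#' @param state Named numeric vector over [iom_state_names()].
#' @param params An [iom_parameters()] list.
#' @param clamp_cac Logical; clamp cytosolic Ca2+?
#' @return List whose first element is the derivative vector (deSolve
#'   convention).
#' @export
iom_rhs_r <- function(t, state, params, clamp_cac = FALSE) {
  s <- as.list(state)
  p <- params
  atpc <- p$actot - s$adpc

  cur <- membrane_currents(s$v, s$n, s$cac, atpc, s$adpc, p)
  mem <- membrane_rhs(s$v, s$n, cur, p)

  jgk <- gk_flux(p$glucose, p)
  jpfk <- pfk_flux(s$f6p, s$fbp, atpc, adp = s$adpc, params = p)
  jgpdh <- gpdh_flux(s$cam, s$fbp, p$kgpdh)
  gly <- glycolysis_rhs(jgk, jpfk, jgpdh, p)

  mf <- mito_fluxes(s$nadhm, s$adpm, s$cam, s$psim, s$cac, jgpdh, s$adpc, p)
  mito <- mito_rhs(mf, p)

  ca <- calcium_compartment_rhs(s$cac, s$caer, cur$ica, mf$juni, mf$jnaca, p)
  dadpc <- nucleotide_rhs(s$adpc, s$cac, mf$jant, p)

  d <- c(mem$dv, mem$dn,
         if (clamp_cac) 0 else ca$dcac,
         ca$dcaer, mito$dcam,
         gly$df6p, gly$dfbp,
         mito$dnadhm, mito$dadpm, mito$dpsim,
         dadpc)
  names(d) <- iom_state_names()
  list(d)
}

#' Derived currents and fluxes along a trajectory
#'
#' Recomputes every ionic current, metabolic flux, and derived
#' concentration (ATP_c, ATP_m, NAD_m, AMP, o_inf) from the state columns
#' of a trajectory data frame.
#'
#' @param states Data frame with columns [iom_state_names()].
#' @param params An [iom_parameters()] list (per-row overrides of `glucose`,
#'   `ktt`, `vk` are taken from columns of `states` if present).
#' @return Data frame of derived series, one row per input row.
#' @export
iom_derived <- function(states, params) {
  p <- params
  atpc <- p$actot - states$adpc
  oinf <- katp_open_fraction(atpc, states$adpc, p$ktt, p$ktd, p$kdd)
  cur <- membrane_currents(states$v, states$n, states$cac, atpc,
                           states$adpc, p)
  jgk <- gk_flux(p$glucose, p)
  jpfk <- pfk_flux(states$f6p, states$fbp, atpc, adp = states$adpc,
                   params = p)
  jgpdh <- gpdh_flux(states$cam, states$fbp, p$kgpdh)
  mf <- mito_fluxes(states$nadhm, states$adpm, states$cam, states$psim,
                    states$cac, jgpdh, states$adpc, p)
  jhyd <- hydrolysis_flux(states$cac, atpc, p)
  data.frame(
    atpc = atpc, atpm = p$amtot - states$adpm,
    nadm = p$nadtot - states$nadhm, amp = states$adpc^2 / atpc,
    oinf = oinf,
    ica = cur$ica, ik = cur$ik, ikca = cur$ikca, ikatp = cur$ikatp,
    jgk = rep_len(jgk, nrow(states)), jpfk = jpfk, jgpdh = jgpdh,
    jpdh = mf$jpdh, jo = mf$jo, jf1f0 = mf$jf1f0, jant = mf$jant,
    jhleak = mf$jhleak, jhres = mf$jhres,
    juni = mf$juni, jnaca = mf$jnaca, jhyd = jhyd
  )
}
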
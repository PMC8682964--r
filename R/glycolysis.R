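## Glycolytic module: glucokinase input, the allosteric PFK step whose FBP
## product-activation generates intrinsic (active) metabolic oscillations,
## and the Ca2+-sensitive GPDH drain.

#' Glucokinase flux
#'
#' Saturating Hill function of bath glucose,
#' \eqn{J_{GK} = v_{GK}\, G^{n}/(K^{n} + G^{n})}; the sole entry point of
#' glucose into the model.
#'
#' @param glucose Bath glucose (mM), >= 0.
#' @param params An [iom_parameters()] list.
#' @return Flux (uM/ms).
#' @export
gk_flux <- function(glucose, params = iom_parameters()) {
  if (any(glucose < 0)) stop("glucose must be >= 0")
  g <- glucose^params$ngk
  params$vgk * g / (params$kgk^params$ngk + g)
}

#' Allosteric phosphofructokinase flux
#'
#' Weighted-binding-state model of tetrameric PFK with activators AMP and
#' FBP (product activation), inhibitor ATP, and substrate F6P; each ligand
#' binds cooperatively (as a squared concentration).  Binding states carrying the substrate catalyze; the
#' fully activated state (AMP and FBP bound, no ATP) at full rate, all
#' others at relative rate \code{lampfk}.  AMP is taken from the
#' adenylate-kinase equilibrium, \eqn{AMP = ADP^2/ATP}, when not supplied.
#'
#' @param f6p Fructose-6-phosphate (uM).
#' @param fbp Fructose-1,6-bisphosphate (uM).
#' @param atp Cytosolic ATP (uM).
#' @param amp Cytosolic AMP (uM); default `adp^2/atp`.
#' @param adp Cytosolic ADP (uM), used only to derive `amp`.
#' @param params An [iom_parameters()] list.
#' @return Flux (uM/ms).
#' @export
pfk_flux <- function(f6p, fbp, atp, amp = NULL, adp = NULL,
                     params = iom_parameters()) {
  p <- params
  if (any(f6p < 0) || any(fbp < 0) || any(atp < 0))
    stop("PFK inputs must be >= 0")
  if (is.null(amp)) {
    if (is.null(adp)) stop("supply either amp or adp")
    if (any(atp == 0)) stop("AMP derivation requires atp > 0")
    amp <- adp^2 / atp
  }
  if (any(amp < 0)) stop("amp must be >= 0")

  ## site occupancy ratios; each ligand binds pairwise (tetramer), hence
  ## the squared concentrations and effective cooperativity 2
  wa <- amp^2 / p$k1
  wf <- fbp^2 / p$k2
  ws <- f6p^2 / p$k3
  wt <- atp^2 / p$k4

  bottom <- 0
  top    <- 0   # lampfk-weighted sum over substrate-bound states
  wact   <- 0   # the fully activated substrate-bound state
  for (i in 0:1) for (j in 0:1) for (k in 0:1) for (l in 0:1) {
    w <- wa^i * wf^j * ws^k * wt^l /
      (p$f13^(i * k) * p$f23^(j * k) *
         p$f41^(i * l) * p$f42^(j * l) * p$f43^(k * l))
    bottom <- bottom + w
    if (k == 1) {
      top <- top + w
      if (i == 1 && j == 1 && l == 0) wact <- w
    }
  }
  p$vpfk * (wact + p$lampfk * (top - wact)) / bottom
}

#' Glycerol-3-phosphate dehydrogenase flux
#'
#' \eqn{J_{GPDH} = \frac{Ca_m^2}{K_{GPDH} + Ca_m^2}\, FBP}: linear in FBP
#' with a saturating mitochondrial-Ca2+ activation (the dehydrogenase arm of
#' Ca2+'s feedback onto metabolism).  The rate constant is absorbed into
#' \code{kgpdh} (uM^2).
#'
#' @param cam Mitochondrial free Ca2+ (uM).
#' @param fbp Fructose-1,6-bisphosphate (uM).
#' @param kgpdh Half-activation constant (uM^2), > 0.
#' @return Flux (uM/ms).
#' @export
gpdh_flux <- function(cam, fbp, kgpdh = iom_parameters()$kgpdh) {
  if (any(cam < 0) || any(fbp < 0)) stop("cam and fbp must be >= 0")
  if (any(kgpdh <= 0)) stop("kgpdh must be > 0")
  cam^2 / (kgpdh + cam^2) * fbp
}

#' Glycolytic state derivatives
#'
#' \eqn{dF6P/dt = \kappa (J_{GK} - J_{PFK})},
#' \eqn{dFBP/dt = J_{PFK} - \tfrac12 J_{GPDH}} (one hexose yields two
#' trioses).  \code{kappa} is the fast G6P/F6P partition fraction.
#'
#' @param jgk,jpfk,jgpdh Fluxes (uM/ms).
#' @param params An [iom_parameters()] list.
#' @return List with `df6p`, `dfbp` (uM/ms).
#' @export
glycolysis_rhs <- function(jgk, jpfk, jgpdh, params = iom_parameters()) {
  list(df6p = params$kappa * (jgk - jpfk),
       dfbp = jpfk - 0.5 * jgpdh)
}
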
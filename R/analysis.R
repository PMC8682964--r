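## Oscillation phenotyping: burst detection, period/amplitude measurement,
## FBP waveform and mechanism classification, episode grouping, psi_m phase
## relation, subthreshold detection.

#' Detect bursts in a membrane-potential trace
#'
#' Active phases are intervals where a smoothed V crosses a two-threshold
#' (hysteresis) criterion: entry above the `enter` quantile of the smoothed
#' trace, exit below the `exit` quantile.  Spikes are counted by peak
#' detection within active phases.
#'
#' @param t Time (min), uniformly sampled.
#' @param v Membrane potential (mV).
#' @param enter,exit Hysteresis quantiles of the smoothed trace.
#' @param smooth_ms Moving-average window (ms).
#' @param min_amp Minimal V range (mV) to consider the trace oscillating.
#' @return List of class `"iom_bursts"`: `active` (data frame of
#'   `start`/`end` in min), `period` (mean onset spacing, min), `duty`
#'   (duty cycle), `spikes` (per-burst spike count), `oscillating`.
#' @export
detect_bursts <- function(t, v, enter = 0.6, exit = 0.4, smooth_ms = 2000,
                          min_amp = 5) {
  stopifnot(length(t) == length(v))
  empty <- list(active = data.frame(start = numeric(0), end = numeric(0)),
                period = NA_real_, duty = NA_real_, spikes = integer(0),
                oscillating = FALSE,
                thresholds = c(enter = NA_real_, exit = NA_real_))
  class(empty) <- "iom_bursts"
  if (length(t) < 10 || diff(range(v)) < min_amp) return(empty)

  dt_ms <- mean(diff(t)) * 60000
  win <- max(1L, round(smooth_ms / dt_ms))
  sv <- stats::filter(v, rep(1 / win, win), sides = 2)
  sv[is.na(sv)] <- v[is.na(sv)]
  hi <- as.numeric(stats::quantile(sv, enter))
  lo <- as.numeric(stats::quantile(sv, exit))
  ## keep both thresholds crossable (a clean square wave puts the upper
  ## quantile exactly on the plateau) and non-degenerate
  rng <- diff(range(sv))
  hi <- min(hi, max(sv) - 0.1 * rng)
  lo <- max(lo, min(sv) + 0.1 * rng)
  if (hi - lo < 0.05 * rng) {
    mid <- (max(sv) + min(sv)) / 2
    hi <- mid + 0.1 * rng; lo <- mid - 0.1 * rng
  }

  state <- sv[1] > hi
  on <- integer(0); off <- integer(0)
  if (state) on <- 1L
  for (i in seq_along(sv)[-1]) {
    if (!state && sv[i] > hi) { state <- TRUE; on <- c(on, i) }
    else if (state && sv[i] < lo) { state <- FALSE; off <- c(off, i) }
  }
  if (length(on) == 0) return(empty)
  if (length(off) < length(on)) off <- c(off, length(sv))
  act <- data.frame(start = t[on], end = t[off])
  ## spike count per burst: local maxima above the entry threshold
  spikes <- vapply(seq_len(nrow(act)), function(k) {
    idx <- which(t >= act$start[k] & t <= act$end[k])
    if (length(idx) < 3) return(0L)
    x <- v[idx]
    sum(diff(sign(diff(x))) == -2 & x[2:(length(x) - 1)] > hi)
  }, integer(1))
  period <- if (nrow(act) > 1) mean(diff(act$start)) else NA_real_
  duty <- sum(act$end - act$start) / diff(range(t))
  out <- list(active = act, period = period, duty = duty, spikes = spikes,
              oscillating = nrow(act) >= 2,
              thresholds = c(enter = hi, exit = lo))
  class(out) <- "iom_bursts"
  out
}

#' @export
print.iom_bursts <- function(x, ...) {
  cat(sprintf("<iom_bursts> %d active phase(s); period %.3g min; duty %.2f\n",
              nrow(x$active), x$period, x$duty))
  invisible(x)
}

#' Period, amplitude, and oscillation verdict of a series
#'
#' Period from the dominant autocorrelation peak (fallback: mean
#' peak-to-peak spacing); amplitude as the mean per-cycle max minus min.
#' A series counts as oscillating when the amplitude exceeds `rel_floor`
#' of the absolute signal mean, sustained over at least three cycles.
#'
#' @param t Time (min), uniform.
#' @param x Signal.
#' @param rel_floor Relative amplitude floor (default 1% of signal mean).
#' @return List: `period` (min), `amplitude`, `oscillating`.
#' @export
measure_period_amplitude <- function(t, x, rel_floor = 0.01) {
  none <- list(period = NA_real_, amplitude = 0, oscillating = FALSE)
  n <- length(x)
  if (n < 8 || stats::sd(x) == 0) return(none)
  dt <- mean(diff(t))
  xc <- x - mean(x)
  ac <- stats::acf(xc, lag.max = floor(n / 2), plot = FALSE)$acf[, 1, 1]
  ## first local max after the first zero crossing / dip
  pk <- which(diff(sign(diff(ac))) == -2) + 1
  pk <- pk[ac[pk] > 0.1]
  period <- if (length(pk)) (pk[1] - 1) * dt else {
    mx <- which(diff(sign(diff(xc))) == -2) + 1
    mx <- mx[xc[mx] > 0.25 * max(xc)]
    if (length(mx) > 2) mean(diff(t[mx])) else NA_real_
  }
  if (!is.finite(period) || period <= 0) return(none)
  ## per-cycle amplitude
  brk <- seq(t[1], t[n], by = period)
  if (length(brk) < 3) return(none)
  cyc <- findInterval(t, brk)
  ## complete cycles only: partial edge cycles dilute the amplitude
  full <- as.integer(names(which(table(cyc) >= 0.9 * period / dt)))
  amp <- vapply(full, function(k) diff(range(x[cyc == k])), numeric(1))
  if (!length(amp)) return(none)
  amplitude <- mean(amp)
  osc <- sum(amp > rel_floor * max(abs(mean(x)), .Machine$double.eps)) >= 3
  list(period = period, amplitude = amplitude, oscillating = osc)
}

#' Classify the FBP waveform
#'
#' Distinguishes the two canonical slow-oscillation FBP shapes: `pulsatile`
#' (sharp peaks that decay to near zero, where FBP remains for much of the
#' cycle -- the active/intrinsic signature) versus `sawtooth` (peak near
#' active-phase onset, nadir at its end, bounded away from zero -- the
#' passive signature).  Pulsatile requires at least `low_frac` of each
#' cycle spent below `low_level` of the cycle peak.
#'
#' @param t Time (min).
#' @param fbp FBP series (uM).
#' @param low_frac Fraction-of-cycle threshold (default 0.3).
#' @param low_level Fraction-of-peak defining "near zero" (default 0.1).
#' @return `"sawtooth"`, `"pulsatile"`, or `"none"`.
#' @export
classify_fbp_waveform <- function(t, fbp, low_frac = 0.3, low_level = 0.1) {
  m <- measure_period_amplitude(t, fbp)
  if (!m$oscillating) return("none")
  brk <- seq(t[1], t[length(t)], by = m$period)
  if (length(brk) < 3) return("none")
  cyc <- findInterval(t, brk)
  fr <- vapply(split(fbp, cyc), function(z) {
    if (length(z) < 3) return(NA_real_)
    mean(z < low_level * max(z))
  }, numeric(1))
  fr <- fr[is.finite(fr)]
  if (mean(fr) >= low_frac) "pulsatile" else "sawtooth"
}

#' Group bursts into episodes (compound bursting)
#'
#' Episodes are maximal runs of bursts whose inter-burst gaps stay below a
#' split threshold (default: a gap larger than `split_factor` times the
#' median gap starts a new episode).  A compound pattern requires at least
#' two episodes of at least two bursts each.
#'
#' @param bursts An [detect_bursts()] result with >= 4 active phases.
#' @param split_factor Gap multiple that splits episodes.
#' @return List: `episodes` (data frame `start`, `end`, `n_bursts`),
#'   `episode_period` (mean episode-onset spacing, min), `compound`.
#' @export
detect_episodes <- function(bursts, split_factor = 2) {
  none <- list(episodes = data.frame(start = numeric(0), end = numeric(0),
                                     n_bursts = integer(0)),
               episode_period = NA_real_, compound = FALSE)
  act <- bursts$active
  if (nrow(act) < 4) return(none)
  gaps <- act$start[-1] - act$end[-nrow(act)]
  thr <- split_factor * stats::median(gaps)
  newep <- c(TRUE, gaps > thr)
  epi <- cumsum(newep)
  ep <- data.frame(
    start = tapply(act$start, epi, min),
    end = tapply(act$end, epi, max),
    n_bursts = as.integer(table(epi)))
  period <- if (nrow(ep) > 1) mean(diff(ep$start)) else NA_real_
  list(episodes = ep, episode_period = period,
       compound = sum(ep$n_bursts >= 2) >= 2 && nrow(ep) >= 2)
}

#' Phase relation of the mitochondrial membrane potential
#'
#' Compares mean psi_m during burst active phases with the silent-phase
#' mean.  Following the plotting convention in which an increase in psi_m
#' denotes hyperpolarization: `"hyperpolarizing"` when the active-phase
#' mean exceeds the silent-phase mean by more than `floor_mV`,
#' `"depolarizing"` for the reverse, `"flat"` otherwise.
#'
#' @param t Time (min).
#' @param psim psi_m series (mV).
#' @param bursts A [detect_bursts()] result.
#' @param floor_mV Noise floor (mV).
#' @return `"hyperpolarizing"`, `"depolarizing"`, or `"flat"`.
#' @export
psi_phase_relation <- function(t, psim, bursts, floor_mV = 0.25) {
  act <- bursts$active
  if (nrow(act) == 0) return("flat")
  in_active <- rep(FALSE, length(t))
  for (k in seq_len(nrow(act)))
    in_active[t >= act$start[k] & t <= act$end[k]] <- TRUE
  if (!any(in_active) || all(in_active)) return("flat")
  d <- mean(psim[in_active]) - mean(psim[!in_active])
  if (d > floor_mV) "hyperpolarizing"
  else if (d < -floor_mV) "depolarizing"
  else "flat"
}

#' Detect subthreshold metabolic oscillations
#'
#' Tests a fixed-glucose trajectory segment for the subthreshold phenotype:
#' no electrical spiking, FBP passing the oscillation test, and nonzero
#' cytosolic Ca2+ fluctuations that stay below `ca_frac` of a stimulated
#' reference amplitude (e.g. the pre-step burst amplitude).
#'
#' @param traj An `iom_trajectory` (or data frame with `t`, `v`, `cac`,
#'   `fbp`).
#' @param ca_ref Reference Ca2+ amplitude (uM); `NULL` skips that test.
#' @param ca_frac Maximal allowed fraction of `ca_ref`.
#' @param spike_mV Spike threshold: V maxima above this count as spikes.
#' @return List: `spiking`, `ca_amplitude`, `fbp_oscillating`, `verdict`.
#' @export
detect_subthreshold <- function(traj, ca_ref = NULL, ca_frac = 0.25,
                                spike_mV = -40) {
  v <- traj$v
  mx <- which(diff(sign(diff(v))) == -2) + 1
  spiking <- any(v[mx] > spike_mV)
  ca_amp <- diff(range(traj$cac))
  fbp <- measure_period_amplitude(traj$t, traj$fbp)
  small <- ca_amp > 0 &&
    (is.null(ca_ref) || ca_amp < ca_frac * ca_ref)
  list(spiking = spiking, ca_amplitude = ca_amp,
       fbp_oscillating = fbp$oscillating,
       verdict = !spiking && fbp$oscillating && small)
}

#' Classify the metabolic-oscillation mechanism (PMO vs AMO)
#'
#' Runs the computational clamp experiment: simulate the unclamped model,
#' clamp cytosolic Ca2+ at `t_clamp`, and watch the metabolic subsystem for
#' `t_post` minutes over a scan of clamp levels spanning the silent- to
#' active-phase Ca2+ range.  The oscillations are *active* (AMO) if FBP
#' oscillations persist at some constant Ca2+ level, *passive* (PMO) if no
#' constant level sustains them.
#'
#' @param params An [iom_parameters()] list that yields oscillations in the
#'   unclamped model.
#' @param levels Clamp levels (uM), or `NULL` for `n_levels` log-spaced
#'   levels between the silent- and active-phase Ca2+ of a control run.
#' @param n_levels Number of scanned levels.
#' @param t_clamp,t_post Clamp onset and post-clamp observation (min).
#' @param init Initial state (default: equilibrated).
#' @param ... Passed to [simulate_iom()].
#' @return List of class `"iom_mechanism"`: `mechanism` ("PMO", "AMO" or
#'   "undetermined"), `levels`, `sustained` (logical per level), and the
#'   control-run FBP period/amplitude.
#' @export
classify_mechanism <- function(params, levels = NULL, n_levels = 8,
                               t_clamp = 15, t_post = 30, init = NULL,
                               ...) {
  if (is.null(init)) init <- equilibrate_iom(params)
  ## unclamped control over the full observation span, so slow rhythms
  ## complete enough cycles for the oscillation test
  ctrl <- simulate_iom(params, t_span = t_clamp + t_post, init = init,
                       out_dt = 1000, ...)
  fbp0 <- measure_period_amplitude(ctrl$t, ctrl$fbp)
  ca0 <- measure_period_amplitude(ctrl$t, ctrl$cac)
  if (!fbp0$oscillating && !ca0$oscillating)
    return(structure(list(mechanism = "undetermined", levels = numeric(0),
                          sustained = logical(0), control = fbp0),
                     class = "iom_mechanism"))
  if (is.null(levels)) {
    lo <- as.numeric(stats::quantile(ctrl$cac, 0.05))
    hi <- as.numeric(stats::quantile(ctrl$cac, 0.95))
    levels <- exp(seq(log(lo), log(hi), length.out = n_levels))
  }
  sustained <- vapply(levels, function(L) {
    tr <- simulate_iom(params,
                       iom_protocol(proto_clamp(t_clamp, L)),
                       t_span = t_clamp + t_post, init = init,
                       out_dt = 1000, ...)
    post <- tr[tr$t >= t_clamp + 5, ]
    m <- measure_period_amplitude(post$t, post$fbp)
    m$oscillating && m$amplitude >= 0.1 * max(fbp0$amplitude, 0.05)
  }, logical(1))
  structure(list(mechanism = if (any(sustained)) "AMO" else "PMO",
                 levels = levels, sustained = sustained, control = fbp0),
            class = "iom_mechanism")
}

#' @export
print.iom_mechanism <- function(x, ...) {
  cat("<iom_mechanism>", x$mechanism, "\n")
  if (length(x$levels))
    cat(paste(sprintf("  %.3g uM: %s", x$levels,
                      ifelse(x$sustained, "sustained", "lost")),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Full oscillation report for a trajectory
#'
#' Runs burst detection, per-signal period/amplitude measurement, FBP
#' waveform classification, episode grouping, and the psi_m phase relation
#' on a simulated trajectory, after discarding an initial transient.
#'
#' @param traj An `iom_trajectory`.
#' @param discard Transient to discard (min; default 20).
#' @param signals State columns to measure.
#' @return List of class `"oscillation_report"`.
#' @export
analyze_trajectory <- function(traj, discard = 20,
                               signals = c("cac", "fbp", "atpc", "psim",
                                           "nadhm")) {
  tr <- traj[traj$t >= discard, ]
  if (nrow(tr) < 10) stop("trajectory too short after transient discard")
  bursts <- detect_bursts(tr$t, tr$v)
  meas <- lapply(signals, function(sn) measure_period_amplitude(tr$t, tr[[sn]]))
  names(meas) <- signals
  episodes <- detect_episodes(bursts)
  rep <- list(
    bursts = bursts,
    episodes = episodes,
    measures = meas,
    fbp_waveform = classify_fbp_waveform(tr$t, tr$fbp),
    psi_phase = psi_phase_relation(tr$t, tr$psim, bursts),
    discard = discard)
  class(rep) <- "oscillation_report"
  rep
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat("<oscillation_report>\n")
  cat(sprintf("  bursts: %d, period %.3g min, duty %.2f\n",
              nrow(x$bursts$active), x$bursts$period, x$bursts$duty))
  cat(sprintf("  compound: %s (episode period %.3g min)\n",
              x$episodes$compound, x$episodes$episode_period))
  cat(sprintf("  FBP waveform: %s;  psi_m phase: %s\n",
              x$fbp_waveform, x$psi_phase))
  for (sn in names(x$measures)) {
    m <- x$measures[[sn]]
    cat(sprintf("  %-6s period %.3g min, amplitude %.4g, oscillating %s\n",
                sn, m$period, m$amplitude, m$oscillating))
  }
  invisible(x)
}

#' Serialize an oscillation report to JSON
#'
#' @param report An `oscillation_report` (or `iom_mechanism`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
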
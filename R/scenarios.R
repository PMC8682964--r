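## Scenario presets encoding the canonical parameter/protocol combinations
## of the model's oscillatory regimes, plus a regime-scan utility.

#' Scenario presets
#'
#' Returns the registry of named scenario presets.  Each preset fully
#' specifies a simulation (parameter overrides, protocol, time span) plus a
#' machine-checkable list of expected phenotypes expressed in terms of the
#' analysis report.
#'
#' The registry covers the canonical regimes: slow bursting with passive
#' (`fig3_pmo`, v_PDH = 0.4) or active (`fig3_amo`, v_PDH = 2) metabolic
#' oscillations; the Ca2+-clamp dichotomy (`fig4_pmo`, `fig4_amo`, clamp at
#' t = 15 min); the diazoxide/KCl matrix (`fig5_a`..`fig5_d`, v_PDH = 7,
#' 3, 2, 0.4, Dz at t = 15, KCl added at t = 45); a glucose step from 11 to
#' 5 mM (`fig6`); compound bursting (`fig7`, g_K(Ca) = 600 pS); and the
#' psi_m phase switch (`fig9_low`/`fig9_high`, p21 = 0.013/0.03).
#'
#' @return Named list of scenario definitions.
#' @export
iom_scenarios <- function() {
  sc <- list(
    fig3_pmo = list(
      desc = "slow bursting, passive metabolic oscillations (v_PDH = 0.4)",
      params = list(vpdh = 0.4, gkca = 150, glucose = 11),
      protocol = iom_protocol(), t_span = 40,
      expect = list(bursting = TRUE, fbp_waveform = "sawtooth")),
    fig3_amo = list(
      desc = "slow bursting, active metabolic oscillations (v_PDH = 2)",
      params = list(vpdh = 2, gkca = 150, glucose = 11),
      protocol = iom_protocol(), t_span = 40,
      expect = list(bursting = TRUE, fbp_waveform = "pulsatile")),
    fig4_pmo = list(
      desc = "Ca2+ clamp at t = 15 min stops all oscillations (PMO)",
      params = list(vpdh = 0.4, gkca = 150, glucose = 11),
      protocol = iom_protocol(proto_clamp(15)), t_span = 45,
      expect = list(post_clamp_quiet = TRUE)),
    fig4_amo = list(
      desc = "Ca2+ clamp at t = 15 min; metabolic oscillations persist (AMO)",
      params = list(vpdh = 2, gkca = 150, glucose = 11),
      protocol = iom_protocol(proto_clamp(15)), t_span = 45,
      expect = list(post_clamp_fbp = TRUE)),
    fig5_a = list(
      desc = "Dz then Dz+KCl, v_PDH = 7: metabolic oscillations persist in Dz",
      params = list(vpdh = 7, gkca = 150, glucose = 11),
      protocol = iom_protocol(proto_dz(15), proto_kcl(45)), t_span = 75,
      expect = list(dz_fbp = TRUE, kcl_fbp = TRUE)),
    fig5_b = list(
      desc = "Dz then Dz+KCl, v_PDH = 3: stop in Dz, re-emerge with KCl",
      params = list(vpdh = 3, gkca = 150, glucose = 11),
      protocol = iom_protocol(proto_dz(15), proto_kcl(45)), t_span = 75,
      expect = list(dz_fbp = FALSE, kcl_fbp = TRUE)),
    fig5_c = list(
      desc = "Dz then Dz+KCl, v_PDH = 2: stop in Dz, no recovery at the KCl level",
      params = list(vpdh = 2, gkca = 150, glucose = 11),
      protocol = iom_protocol(proto_dz(15), proto_kcl(45)), t_span = 75,
      expect = list(dz_fbp = FALSE, kcl_fbp = FALSE, mechanism = "AMO")),
    fig5_d = list(
      desc = "Dz then Dz+KCl, v_PDH = 0.4: stop in Dz, no recovery (PMO)",
      params = list(vpdh = 0.4, gkca = 150, glucose = 11),
      protocol = iom_protocol(proto_dz(15), proto_kcl(45)), t_span = 75,
      expect = list(dz_fbp = FALSE, kcl_fbp = FALSE, mechanism = "PMO")),
    fig6 = list(
      desc = "glucose 11 -> 5 mM at t = 10 min: subthreshold oscillations",
      params = list(vpdh = 2, gkca = 150, glucose = 11),
      protocol = iom_protocol(proto_glucose(10, 5)), t_span = 40,
      expect = list(subthreshold = TRUE)),
    fig7 = list(
      desc = "compound bursting (v_PDH = 2, g_K(Ca) = 600 pS)",
      params = list(vpdh = 2, gkca = 600, glucose = 11),
      protocol = iom_protocol(), t_span = 60,
      expect = list(compound = TRUE)),
    fig9_low = list(
      desc = "p21 = 0.013: psi_m hyperpolarizes during active phases",
      params = list(vpdh = 0.4, gkca = 150, glucose = 11, p21 = 0.013),
      protocol = iom_protocol(), t_span = 40,
      expect = list(bursting = TRUE, psi_phase = "hyperpolarizing")),
    fig9_high = list(
      desc = "p21 = 0.03: psi_m depolarizes during active phases",
      params = list(vpdh = 0.4, gkca = 150, glucose = 11, p21 = 0.03),
      protocol = iom_protocol(), t_span = 40,
      expect = list(bursting = TRUE, psi_phase = "depolarizing"))
  )
  sc
}

#' Run a scenario preset
#'
#' Simulates the named preset (equilibrating first), analyzes the
#' trajectory, and evaluates the preset's expected-phenotype assertions.
#'
#' @param id Preset name; see [iom_scenarios()].
#' @param discard Transient discard for analysis (min).
#' @param ... Passed to [simulate_iom()] (e.g. solver options).
#' @return List of class `"iom_scenario_result"`: `trajectory`, `report`,
#'   `assertions` (named logical), `passed`.
#' @export
run_scenario <- function(id, discard = 20, ...) {
  reg <- iom_scenarios()
  if (!id %in% names(reg))
    stop("unknown scenario '", id, "'; available: ",
         paste(names(reg), collapse = ", "))
  sc <- reg[[id]]
  params <- do.call(iom_parameters, sc$params)
  init <- equilibrate_iom(params, ...)
  traj <- simulate_iom(params, sc$protocol, t_span = sc$t_span,
                       init = init, ...)
  report <- analyze_trajectory(traj, discard = min(discard, sc$t_span / 2))
  assertions <- evaluate_expectations(sc, params, traj, report, init, ...)
  structure(list(id = id, trajectory = traj, report = report,
                 assertions = assertions, passed = all(unlist(assertions))),
            class = "iom_scenario_result")
}

## window helper: oscillation test on a time window of a trajectory
window_osc <- function(traj, from, to, signal = "fbp", min_amp = 0.05) {
  tr <- traj[traj$t >= from & traj$t <= to, ]
  m <- measure_period_amplitude(tr$t, tr[[signal]])
  m$oscillating && m$amplitude > min_amp
}

evaluate_expectations <- function(sc, params, traj, report, init, ...) {
  ex <- sc$expect
  out <- list()
  tsp <- sc$t_span
  for (nm in names(ex)) {
    out[[nm]] <- switch(nm,
      bursting = identical(report$bursts$oscillating, TRUE) &&
        is.finite(report$bursts$period),
      fbp_waveform = identical(report$fbp_waveform, ex$fbp_waveform),
      psi_phase = identical(report$psi_phase, ex$psi_phase),
      compound = identical(report$episodes$compound, ex$compound),
      post_clamp_quiet = {
        post <- traj[traj$t >= 25, ]
        all(vapply(c("cac", "fbp", "atpc", "psim"), function(sn) {
          x <- post[[sn]]; diff(range(x)) < 1e-3 * max(abs(mean(x)), 1e-9)
        }, logical(1)))
      },
      post_clamp_fbp = {
        pre <- traj[traj$t >= 5 & traj$t <= 15, ]
        post <- traj[traj$t >= 25, ]
        a0 <- measure_period_amplitude(pre$t, pre$fbp)
        a1 <- measure_period_amplitude(post$t, post$fbp)
        isTRUE(a1$oscillating) && a1$amplitude >= 0.5 * a0$amplitude
      },
      dz_fbp = window_osc(traj, 20, 45) == ex$dz_fbp,
      kcl_fbp = window_osc(traj, 50, tsp) == ex$kcl_fbp,
      mechanism = {
        mech <- classify_mechanism(params, init = init, ...)
        identical(mech$mechanism, ex$mechanism)
      },
      subthreshold = {
        pre <- traj[traj$t >= 2 & traj$t <= 10, ]
        post <- traj[traj$t >= 20, ]
        st <- detect_subthreshold(post, ca_ref = diff(range(pre$cac)))
        identical(st$verdict, ex$subthreshold)
      },
      stop("unknown expectation: ", nm))
  }
  out
}

#' @export
print.iom_scenario_result <- function(x, ...) {
  cat(sprintf("<iom_scenario> %s: %s\n", x$id,
              if (x$passed) "PASS" else "FAIL"))
  for (nm in names(x$assertions))
    cat(sprintf("  %-18s %s\n", nm, x$assertions[[nm]]))
  invisible(x)
}

#' Scan a parameter grid and label dynamical regimes
#'
#' Simulates every cell of a parameter grid, analyzes each trajectory, and
#' assigns one regime label per cell: `compound` (episodes detected),
#' `slow_AMO` / `slow_PMO` (slow bursting, mechanism from the Ca2+-clamp
#' experiment), `fast_bursting` (burst period < 1 min without episodes),
#' `subthreshold_AMO` (no spiking but FBP oscillating), else `quiescent`.
#'
#' @param axes Named list of parameter value vectors (the grid axes).
#' @param base Base parameters ([iom_parameters()]).
#' @param t_span Simulated span per cell (min).
#' @param discard Transient discard (min).
#' @param classify_slow Run the (expensive) clamp experiment to split
#'   slow_AMO/slow_PMO; if `FALSE`, slow bursting is labeled `slow`.
#' @param max_cells Refuse grids larger than this.
#' @param ... Passed to [simulate_iom()].
#' @return Data frame of class `"iom_regime_map"`: one row per cell with
#'   the axis values, `regime`, and summary metrics.
#' @export
regime_scan <- function(axes, base = iom_parameters(), t_span = 40,
                        discard = 20, classify_slow = TRUE,
                        max_cells = 64, ...) {
  stopifnot(is.list(axes), length(axes) >= 1, !is.null(names(axes)))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) > max_cells)
    stop("grid has ", nrow(grid), " cells; budget is ", max_cells)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base
    for (nm in names(axes)) p[[nm]] <- grid[[nm]][i]
    validate_parameters(p)
    init <- equilibrate_iom(p, ...)
    traj <- simulate_iom(p, t_span = t_span, init = init, ...)
    rep <- analyze_trajectory(traj, discard = discard)
    ca <- rep$measures$cac
    fbp <- rep$measures$fbp
    label <-
      if (rep$episodes$compound) "compound"
      else if (rep$bursts$oscillating && is.finite(rep$bursts$period)) {
        if (rep$bursts$period < 1) "fast_bursting"
        else if (!classify_slow) "slow"
        else {
          mech <- classify_mechanism(p, init = init, ...)
          if (mech$mechanism == "AMO") "slow_AMO" else "slow_PMO"
        }
      } else {
        st <- detect_subthreshold(traj[traj$t >= discard, ])
        if (st$verdict || (!st$spiking && st$fbp_oscillating))
          "subthreshold_AMO" else "quiescent"
      }
    cbind(grid[i, , drop = FALSE],
          data.frame(regime = label,
                     burst_period = rep$bursts$period,
                     episode_period = rep$episodes$episode_period,
                     ca_amplitude = fifelse_na(ca$amplitude),
                     fbp_amplitude = fifelse_na(fbp$amplitude),
                     fbp_waveform = rep$fbp_waveform))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "axes") <- axes
  attr(out, "t_span") <- t_span
  class(out) <- c("iom_regime_map", "data.frame")
  out
}

fifelse_na <- function(x) if (is.null(x) || !is.finite(x)) NA_real_ else x

#' Write a regime map (CSV + JSON metadata sidecar)
#'
#' @param map An `iom_regime_map`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_regime_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  meta <- list(axes = attr(map, "axes"), t_span = attr(map, "t_span"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
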
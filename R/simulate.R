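## Stiff integration of the full model, piecewise between protocol events.

#' Simulate the Integrated Oscillator Model
#'
#' Integrates the 11-variable stiff ODE system over `t_span` minutes,
#' applying protocol events as piecewise parameter overrides or cytosolic
#' Ca2+ clamps.  The solver is restarted at every event with the pre-event
#' state (state continuous, parameters discontinuous).  Output is sampled
#' on a uniform grid and includes all state variables plus derived
#' concentrations, fluxes, and currents recomputed at the output times.
#'
#' @param params An [iom_parameters()] list.
#' @param protocol An [iom_protocol()]; default control (no events).
#' @param t_span Simulated span (min).
#' @param init Named initial state over [iom_state_names()], or \code{NULL}
#'   to start from [equilibrate_iom()].
#' @param out_dt Output cadence (ms); default 100.
#' @param rtol,atol Solver tolerances.
#' @param method deSolve method; default \code{"lsoda"}.
#' @param engine \code{"compiled"} (C right-hand side) or \code{"R"}
#'   (reference implementation; much slower).
#' @param equil_min Equilibration span (min) when `init` is NULL.
#' @return Data frame of class \code{"iom_trajectory"}: column `t` (min),
#'   the state columns, derived series, and annotation columns `segment`
#'   and `clamped`.  Attributes: `params`, `protocol`, `solver`.
#' @export
simulate_iom <- function(params = iom_parameters(),
                         protocol = iom_protocol(),
                         t_span = 30,
                         init = NULL,
                         out_dt = 100,
                         rtol = 1e-8, atol = 1e-10,
                         method = "lsoda",
                         engine = c("compiled", "R"),
                         equil_min = 20) {
  engine <- match.arg(engine)
  if (t_span <= 0) stop("t_span must be > 0 (minutes)")
  validate_parameters(params)
  if (is.null(init))
    init <- equilibrate_iom(params, t_equil = equil_min, rtol = rtol,
                            atol = atol, method = method, engine = engine)
  if (!all(iom_state_names() %in% names(init)))
    stop("init must be named over iom_state_names()")
  init <- init[iom_state_names()]

  t_end <- t_span * 60000
  ev <- protocol$events
  ev_t <- vapply(ev, function(e) e$time * 60000, numeric(1))
  keep <- ev_t < t_end
  ev <- ev[keep]; ev_t <- ev_t[keep]
  bounds <- c(0, ev_t, t_end)

  grid <- seq(0, t_end, by = out_dt)
  p <- params
  clamp <- FALSE
  clamp_level <- 0
  state <- init
  rows <- vector("list", length(bounds) - 1)
  ann <- vector("list", length(bounds) - 1)
  stats <- list()

  for (seg in seq_len(length(bounds) - 1)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1]
    if (seg > 1) {   # apply the event opening this segment
      e <- ev[[seg - 1]]
      if (e$action == "set_parameter") {
        p[[e$name]] <- e$value
      } else if (e$action == "clamp_cac") {
        lev <- e$value
        if (is.na(lev)) {
          prev <- do.call(rbind, rows[seq_len(seg - 1)])
          win <- prev[prev[, "time"] >= t0 - 5 * 60000, "cac"]
          lev <- as.numeric(stats::quantile(win, 0.1, names = FALSE))
        }
        clamp <- TRUE; clamp_level <- lev
        state["cac"] <- lev
      } else if (e$action == "release_clamp") {
        clamp <- FALSE
      }
    }
    times <- unique(c(t0, grid[grid > t0 & grid < t1], t1))
    out <- run_segment(state, times, p, clamp, clamp_level,
                       rtol, atol, method, engine)
    state <- out[nrow(out), iom_state_names()]
    names(state) <- iom_state_names()
    keep_rows <- if (seg < length(bounds) - 1) out[, "time"] < t1
                 else rep(TRUE, nrow(out))
    rows[[seg]] <- out[keep_rows, , drop = FALSE]
    ann[[seg]] <- list(n = sum(keep_rows), segment = seg,
                       clamped = clamp, params = p)
  }

  states <- as.data.frame(do.call(rbind, rows))
  names(states)[1] <- "t"
  derived <- do.call(rbind, lapply(seq_along(ann), function(i) {
    a <- ann[[i]]
    idx <- (if (i == 1) 0 else sum(vapply(ann[seq_len(i - 1)],
                                          `[[`, numeric(1), "n"))) +
           seq_len(a$n)
    iom_derived(states[idx, , drop = FALSE], a$params)
  }))
  traj <- cbind(states, derived)
  traj$segment <- rep(vapply(ann, `[[`, numeric(1), "segment"),
                      vapply(ann, `[[`, numeric(1), "n"))
  traj$clamped <- rep(vapply(ann, function(a) as.numeric(a$clamped),
                             numeric(1)),
                      vapply(ann, `[[`, numeric(1), "n"))
  traj$t <- traj$t / 60000   # -> minutes
  attr(traj, "params") <- params
  attr(traj, "protocol") <- protocol
  attr(traj, "solver") <- list(method = method, rtol = rtol, atol = atol,
                               out_dt = out_dt, engine = engine)
  class(traj) <- c("iom_trajectory", "data.frame")
  traj
}

run_segment <- function(state, times, p, clamp, clamp_level,
                        rtol, atol, method, engine) {
  out <- if (engine == "compiled") {
    deSolve::ode(y = unname(state), times = times, func = "iom_derivs",
                 parms = param_vector(p, clamp, clamp_level),
                 dllname = "betaburst", initfunc = "iom_init",
                 method = method, rtol = rtol, atol = atol,
                 maxsteps = 1e6)
  } else {
    if (clamp) state["cac"] <- clamp_level
    deSolve::ode(y = state, times = times,
                 func = function(t, y, parms) iom_rhs_r(t, y, p, clamp),
                 parms = NULL, method = method, rtol = rtol, atol = atol,
                 maxsteps = 1e6)
  }
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf(
      "integration failed in segment [%g, %g] min (istate = %d); state: %s",
      times[1] / 60000, times[length(times)] / 60000, istate[1],
      paste(sprintf("%s=%.4g", iom_state_names(),
                    out[nrow(out), -1]), collapse = ", ")))
  colnames(out) <- c("time", iom_state_names())
  unclass(out)
}

#' Equilibrate the model
#'
#' Integrates from the documented default state ([iom_initial_state()]) for
#' a fixed transient and returns the final state, for use as an initial
#' condition.  Deterministic: repeated calls give identical results.
#'
#' @inheritParams simulate_iom
#' @param ... Ignored (accepted so simulation options can be passed
#'   through wholesale by callers).
#' @param t_equil Transient length (min); default 20, matching the
#'   transient-discard convention of the analysis layer.
#' @return Named state vector.
#' @export
equilibrate_iom <- function(params = iom_parameters(), t_equil = 20,
                            rtol = 1e-8, atol = 1e-10, method = "lsoda",
                            engine = c("compiled", "R"), ...) {
  engine <- match.arg(engine)
  validate_parameters(params)
  times <- c(0, t_equil * 60000)
  out <- run_segment(iom_initial_state(), times, params, FALSE, 0,
                     rtol, atol, method, engine)
  state <- out[nrow(out), iom_state_names()]
  names(state) <- iom_state_names()
  state
}

## ---- trajectory I/O --------------------------------------------------------

## internal column name -> external CSV header
.csv_names <- c(
  t = "t_min", v = "V_mV", n = "n", cac = "Ca_c_uM", caer = "Ca_er_uM",
  cam = "Ca_m_uM", f6p = "F6P_uM", fbp = "FBP_uM", nadhm = "NADH_m_uM",
  adpm = "ADP_m_uM", psim = "psi_m_mV", adpc = "ADP_c_uM",
  atpc = "ATP_c_uM", atpm = "ATP_m_uM", nadm = "NAD_m_uM", amp = "AMP_uM",
  oinf = "o_inf",
  ica = "I_Ca_fA", ik = "I_K_fA", ikca = "I_KCa_fA", ikatp = "I_KATP_fA",
  jgk = "J_GK_uMms", jpfk = "J_PFK_uMms", jgpdh = "J_GPDH_uMms",
  jpdh = "J_PDH_uMms", jo = "J_O_uMms", jf1f0 = "J_F1F0_uMms",
  jant = "J_ANT_uMms", jhleak = "J_Hleak_uMms", jhres = "J_Hres_uMms",
  juni = "J_uni_uMms", jnaca = "J_NaCa_uMms", jhyd = "J_hyd_uMms",
  segment = "segment", clamped = "clamped")

#' Write / read a trajectory
#'
#' `write_trajectory()` writes the sampled series as CSV plus a JSON
#' sidecar (`<path>.json`) holding the resolved parameter set, protocol,
#' and solver settings.  `read_trajectory()` restores the object.
#'
#' @param traj An `iom_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory()`: `path`, invisibly. `read_trajectory()`:
#'   an `iom_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  names(df) <- unname(.csv_names[names(df)])
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    params = unclass(attr(traj, "params")),
    protocol = protocol_table(attr(traj, "protocol")),
    solver = attr(traj, "solver"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  inv <- stats::setNames(names(.csv_names), unname(.csv_names))
  names(df) <- unname(inv[names(df)])
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pars <- iom_parameters()
    pars[names(meta$params)] <- meta$params
    attr(df, "params") <- pars
    attr(df, "solver") <- meta$solver
  }
  class(df) <- c("iom_trajectory", "data.frame")
  df
}

#' @export
print.iom_trajectory <- function(x, ...) {
  cat(sprintf("<iom_trajectory> %d samples, %.4g-%.4g min, %d segments\n",
              nrow(x), min(x$t), max(x$t), max(x$segment)))
  invisible(x)
}

#' Plot a trajectory
#'
#' Stacked panels of selected series against time, in the style of the
#' model's standard figures.
#'
#' @param x An `iom_trajectory`.
#' @param vars Column names to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.iom_trajectory <- function(x, vars = c("v", "cac", "fbp", "atpc"),
                                ...) {
  vars <- intersect(vars, names(x))
  op <- graphics::par(mfrow = c(length(vars), 1),
                      mar = c(2.5, 4, 0.5, 0.5))
  on.exit(graphics::par(op))
  for (vn in vars)
    graphics::plot(x$t, x[[vn]], type = "l", xlab = "", ylab = vn, ...)
  invisible(x)
}
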
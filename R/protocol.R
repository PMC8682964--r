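## Declarative in-silico protocols: timed parameter overrides and cytosolic
## Ca2+ clamps applied piecewise during a simulation.

#' Build a timed experimental protocol
#'
#' A protocol is an ordered list of events, each created by one of the
#' constructors below.  Event times are in minutes and must be strictly
#' increasing.  Named shortcuts follow the standard pharmacology:
#' diazoxide opens K(ATP) channels (modeled as raising the ATP dissociation
#' constant \code{ktt} from 1 to 2 uM), KCl depolarizes (raising the K+
#' Nernst potential \code{vk} from -75 to -70 mV).
#'
#' @param ... Events from [proto_set()], [proto_glucose()], [proto_dz()],
#'   [proto_kcl()], [proto_clamp()], [proto_release()].
#' @return An object of class \code{"iom_protocol"} (possibly empty: the
#'   control protocol).
#' @examples
#' iom_protocol(proto_dz(15), proto_kcl(30))
#' @export
iom_protocol <- function(...) {
  events <- list(...)
  for (e in events)
    if (!inherits(e, "iom_event"))
      stop("protocol events must be built with the proto_*() constructors")
  tt <- vapply(events, function(e) e$time, numeric(1))
  if (length(tt) && any(diff(tt) <= 0))
    stop("event times must be strictly increasing")
  if (length(tt) && any(tt < 0)) stop("event times must be >= 0")
  structure(list(events = events), class = "iom_protocol")
}

new_event <- function(time, action, name = NA_character_, value = NA_real_) {
  if (!is.numeric(time) || length(time) != 1 || !is.finite(time))
    stop("event time must be a finite number (minutes)")
  structure(list(time = time, action = action, name = name, value = value),
            class = "iom_event")
}

#' @rdname iom_protocol
#' @param time Event time (min).
#' @param name Parameter name (must exist in [iom_parameters()]).
#' @param value New parameter value.
#' @export
proto_set <- function(time, name, value) {
  if (!name %in% names(iom_parameters()))
    stop("unknown parameter: ", name)
  new_event(time, "set_parameter", name, value)
}

#' @rdname iom_protocol
#' @param mM Glucose concentration (mM).
#' @export
proto_glucose <- function(time, mM) {
  if (mM < 0) stop("glucose must be >= 0")
  new_event(time, "set_parameter", "glucose", mM)
}

#' @rdname iom_protocol
#' @param on Logical: apply (TRUE) or wash out (FALSE).
#' @export
proto_dz <- function(time, on = TRUE) {
  new_event(time, "set_parameter", "ktt", if (on) 2 else 1)
}

#' @rdname iom_protocol
#' @export
proto_kcl <- function(time, on = TRUE) {
  new_event(time, "set_parameter", "vk", if (on) -70 else -75)
}

#' @rdname iom_protocol
#' @param level Clamp level (uM), or \code{NULL} to clamp at the
#'   silent-phase cytosolic Ca2+ observed just before the event (the 10th
#'   percentile of Ca_c over the preceding 5 min).
#' @export
proto_clamp <- function(time, level = NULL) {
  if (!is.null(level) && level <= 0) stop("clamp level must be > 0")
  new_event(time, "clamp_cac", value = if (is.null(level)) NA_real_
            else level)
}

#' @rdname iom_protocol
#' @export
proto_release <- function(time) new_event(time, "release_clamp")

#' @export
print.iom_protocol <- function(x, ...) {
  if (!length(x$events)) {
    cat("<iom_protocol> control (no events)\n")
    return(invisible(x))
  }
  cat("<iom_protocol> ", length(x$events), " event(s)\n", sep = "")
  for (e in x$events) {
    desc <- switch(e$action,
      set_parameter = sprintf("set %s = %g", e$name, e$value),
      clamp_cac = if (is.na(e$value)) "clamp Ca_c (silent-phase level)"
                  else sprintf("clamp Ca_c at %g uM", e$value),
      release_clamp = "release Ca_c clamp")
    cat(sprintf("  t = %6.2f min  %s\n", e$time, desc))
  }
  invisible(x)
}

## serializable summary used in trajectory metadata
protocol_table <- function(protocol) {
  if (!length(protocol$events))
    return(data.frame(time = numeric(0), action = character(0),
                      name = character(0), value = numeric(0)))
  do.call(rbind, lapply(protocol$events, function(e)
    data.frame(time = e$time, action = e$action, name = e$name,
               value = e$value)))
}
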
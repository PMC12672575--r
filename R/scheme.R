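#' Illumination, time windows and pulse schemes
#'
#' A pulse scheme is the experimental protocol as data: an ordered list of
#' time windows, each with a fixed set of simultaneously active lasers, and
#' a repeat count. Within a window the kinetic rates are constant, so the
#' populations can be propagated exactly.
#'
#' @param wavelength Wavelength in nm (one of 405, 488, 592, 810, 900, 915).
#' @param power Power density in W/cm^2.
#' @return `illumination()` returns an `illumination` object.
#' @export
illumination <- function(wavelength, power) {
  if (!wavelength %in% SUPPORTED_WAVELENGTHS)
    stop("unsupported wavelength ", wavelength, " nm; supported: ",
         paste(SUPPORTED_WAVELENGTHS, collapse = ", "))
  if (power < 0) stop("power density must be >= 0")
  structure(list(wavelength = wavelength, power = power),
            class = "illumination")
}

#' @rdname illumination
#' @param duration Window duration in seconds (> 0).
#' @param illums List of `illumination` objects; empty list means dark.
#' @export
time_window <- function(duration, illums = list()) {
  if (duration <= 0) stop("window duration must be > 0")
  if (inherits(illums, "illumination")) illums <- list(illums)
  stopifnot(all(vapply(illums, inherits, TRUE, "illumination")))
  structure(list(duration = duration, illums = illums),
            class = "time_window")
}

#' @rdname illumination
#' @param windows List of `time_window` objects (non-empty).
#' @param repeats Repeat count (>= 1).
#' @param label Free-text label.
#' @export
pulse_scheme <- function(windows, repeats = 1, label = "") {
  if (inherits(windows, "time_window")) windows <- list(windows)
  if (length(windows) == 0) stop("pulse scheme must contain >= 1 window")
  stopifnot(all(vapply(windows, inherits, TRUE, "time_window")),
            repeats >= 1)
  structure(list(windows = windows, repeats = as.integer(repeats),
                 label = label),
            class = "pulse_scheme")
}

#' @export
print.pulse_scheme <- function(x, ...) {
  cat(sprintf("<pulse_scheme> '%s' x%d\n", x$label, x$repeats))
  for (w in x$windows) {
    il <- if (length(w$illums) == 0) "dark" else
      paste(vapply(w$illums, function(i)
        sprintf("%g nm @ %g W/cm2", i$wavelength, i$power), ""),
        collapse = " + ")
    cat(sprintf("  %10.4g ms  %s\n", w$duration * 1e3, il))
  }
  invisible(x)
}

scheme_duration <- function(scheme) {
  sum(vapply(scheme$windows, `[[`, 0, "duration")) * scheme$repeats
}

## ---- structured-text (YAML) scheme config ------------------------------

POWER_UNITS <- c("W/cm^2" = 1, "W/cm2" = 1, "kW/cm^2" = 1e3, "kW/cm2" = 1e3)
TIME_UNITS  <- c(s = 1, ms = 1e-3, us = 1e-6)

parse_quantity <- function(q, units, what) {
  if (!is.list(q) || is.null(q$value) || is.null(q$unit))
    stop("missing value/unit for ", what, " (units must be explicit)")
  u <- units[as.character(q$unit)]
  if (is.na(u)) stop("unknown ", what, " unit '", q$unit, "'")
  as.numeric(q$value) * unname(u)
}

#' Read / write a pulse scheme config
#'
#' Schemes are stored as YAML: a `label`, a `repeats` count and a list of
#' `windows`, each with a `duration` (`value` + `unit`, unit `s`/`ms`/`us`)
#' and a possibly empty `illuminations` list of `wavelength_nm` plus
#' `power` (`value` + `unit`, unit `W/cm^2` or `kW/cm^2`). Units are
#' mandatory; files without them are rejected.
#'
#' @param path File path.
#' @return `read_scheme()` returns a `pulse_scheme`.
#' @export
read_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$windows) || length(cfg$windows) == 0)
    stop("scheme config has no windows")
  windows <- lapply(cfg$windows, function(w) {
    dur <- parse_quantity(w$duration, TIME_UNITS, "duration")
    ills <- lapply(w$illuminations, function(il) {
      if (is.null(il$wavelength_nm)) stop("illumination missing wavelength_nm")
      illumination(as.numeric(il$wavelength_nm),
                   parse_quantity(il$power, POWER_UNITS, "power"))
    })
    time_window(dur, ills)
  })
  pulse_scheme(windows,
               repeats = if (is.null(cfg$repeats)) 1 else cfg$repeats,
               label = if (is.null(cfg$label)) "" else cfg$label)
}

#' @rdname read_scheme
#' @param scheme A `pulse_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  cfg <- list(
    label = scheme$label,
    repeats = scheme$repeats,
    windows = lapply(scheme$windows, function(w) {
      list(duration = list(value = w$duration * 1e3, unit = "ms"),
           illuminations = lapply(w$illums, function(il)
             list(wavelength_nm = il$wavelength,
                  power = list(value = il$power, unit = "W/cm^2"))))
    }))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
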